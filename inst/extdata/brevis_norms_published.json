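{
  "version": "published-1.0",
  "normative_sample": {
    "n": 550,
    "age_range": [20, 79]
  },
  "models": {
    "SA": {
      "terms": [
        {
          "predictor": "age",
          "transform": {
            "family": "reflected_log",
            "offset": 86.9
          },
          "coefficient": 13.796,
          "center": 3.628
        },
        {
          "predictor": "education",
          "transform": {
            "family": "inverse",
            "offset": null
          },
          "coefficient": -129.5,
          "center": 0.081
        }
      ],
      "fit": {
        "r2": 0.238,
        "adj_r2": 0.236,
        "rse": 16.01
      }
    },
    "OA": {
      "terms": [
        {
          "predictor": "age",
          "transform": {
            "family": "cube",
            "offset": null
          },
          "coefficient": -4e-05,
          "center": 129295
        }
      ],
      "fit": {
        "r2": 0.041,
        "adj_r2": 0.039,
        "rse": 23.38
      }
    },
    "FA": {
      "terms": [
        {
          "predictor": "age",
          "transform": {
            "family": "cube",
            "offset": null
          },
          "coefficient": -1.9e-05,
          "center": 129295
        }
      ],
      "fit": {
        "r2": 0.017,
        "adj_r2": 0.015,
        "rse": 18.11
      }
    },
    "Err": {
      "terms": [
        {
          "predictor": "age",
          "transform": {
            "family": "inverse",
            "offset": null
          },
          "coefficient": 195.11,
          "center": 0.0251
        },
        {
          "predictor": "education",
          "transform": {
            "family": "inverse",
            "offset": null
          },
          "coefficient": -38.13,
          "center": 0.0812
        },
        {
          "predictor": "gender",
          "transform": {
            "family": "identity",
            "offset": null
          },
          "coefficient": 2.6,
          "center": 0.47
        }
      ],
      "fit": {
        "r2": 0.091,
        "adj_r2": 0.086,
        "rse": 8.83
      }
    }
  },
  "tables": {
    "SA": {
      "itl": 90,
      "otl": 97.4,
      "es_cuts": [97.4, 74.8, 67.1, 61.5],
      "percentile_ranks": [99, 95, 90, 85, 80, 75, 70, 65, 60, 55, 50, 45, 40, 35, 30, 25, 20, 15, 10, 5, 4, 3, 2, 1],
      "percentile_values": [38.4, 42.2, 45.5, 47.6, 50.7, 52.5, 54, 55.8, 57.4, 59.9, 61.5, 63.1, 65, 67.1, 69.7, 71.6, 74, 77.8, 83.7, 92.5, 96.9, 98, 102.1, 114.1]
    },
    "OA": {
      "itl": 86.1,
      "otl": 98.8,
      "es_cuts": [98.8, 67.9, 55.6, 46.2],
      "percentile_ranks": [99, 95, 90, 85, 80, 75, 70, 65, 60, 55, 50, 45, 40, 35, 30, 25, 20, 15, 10, 5, 4, 3, 2, 1],
      "percentile_values": [4.5, 12.9, 22.2, 27.2, 30.2, 34.1, 36.4, 38.2, 41.3, 44, 46.2, 48.6, 51.5, 55.1, 58.4, 61, 66.7, 72.9, 78.9, 88.5, 95.1, 100.8, 107.7, 120.3]
    },
    "FA": {
      "itl": 41,
      "otl": 49.2,
      "es_cuts": [49.2, 24.8, 15.5, 8.4],
      "percentile_ranks": [99, 95, 90, 85, 80, 75, 70, 65, 60, 55, 50, 45, 40, 35, 30, 25, 20, 15, 10, 5, 4, 3, 2, 1],
      "percentile_values": [-29.3, -13.7, -8.8, -4.9, -2.7, -0.5, 1.4, 2.9, 4.9, 6.4, 8.4, 10.7, 13.5, 15.4, 17.3, 19.6, 23.6, 27.4, 32.8, 44.1, 45.6, 50.9, 56.5, 60.5]
    },
    "Err": {
      "itl": 29.9,
      "otl": 35.2,
      "es_cuts": [35.2, 23.1, 18.1, 14.7],
      "percentile_ranks": [99, 95, 90, 85, 80, 75, 70, 65, 60, 55, 50, 45, 40, 35, 30, 25, 20, 15, 10, 5, 4, 3, 2, 1],
      "percentile_values": [1, 4.3, 6.1, 7.4, 8.3, 9.9, 10.9, 11.9, 12.9, 13.7, 14.7, 15.9, 16.7, 18, 19.2, 20.3, 22.6, 24.3, 27.5, 31.3, 33.5, 35.5, 38.1, 45]
    }
  }
}
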