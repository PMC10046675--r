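# Printed normative tables used as test fixtures, and small cohort builders.

grid_ages <- seq(22, 77, by = 5)
grid_edus <- c(8, 13, 16, 18, 21)

# SA correction grid (ages x educations 8/13/16/18/21)
published_sa_grid <- rbind(
  c(1.8, 8, 9.9, 10.8, 11.8), c(0.7, 6.9, 8.8, 9.7, 10.7),
  c(-0.5, 5.7, 7.6, 8.5, 9.5), c(-1.8, 4.4, 6.3, 7.2, 8.2),
  c(-3.3, 3, 4.8, 5.7, 6.8), c(-4.9, 1.3, 3.2, 4.1, 5.1),
  c(-6.7, -0.5, 1.4, 2.3, 3.3), c(-8.9, -2.6, -0.8, 0.1, 1.1),
  c(-11.4, -5.2, -3.3, -2.4, -1.4), c(-14.5, -8.3, -6.4, -5.5, -4.5),
  c(-18.5, -12.3, -10.4, -9.5, -8.5), c(-24.1, -17.9, -16, -15.1, -14.1))

# OA / FA correction grids (per age)
published_oa_grid <- c(4.7, 4.4, 3.9, 3.1, 2.2, 1, -0.5, -2.2, -4.4, -6.9, -9.8, -13.1)
published_fa_grid <- c(2.3, 2.1, 1.8, 1.5, 1, 0.5, -0.2, -1.1, -2.1, -3.3, -4.6, -6.2)

# Err correction grids, female and male blocks (ages x educations)
published_err_grid_f <- rbind(
  c(1.1, 2.9, 3.5, 3.7, 4), c(-0.6, 1.3, 1.8, 2.1, 2.4),
  c(-1.7, 0.1, 0.7, 1, 1.3), c(-2.5, -0.7, -0.1, 0.1, 0.4),
  c(-3.1, -1.3, -0.8, -0.5, -0.2), c(-3.6, -1.8, -1.3, -1, -0.7),
  c(-4, -2.2, -1.7, -1.4, -1.1), c(-4.4, -2.5, -2, -1.7, -1.4),
  c(-4.6, -2.8, -2.3, -2, -1.7), c(-4.9, -3, -2.5, -2.2, -1.9),
  c(-5.1, -3.2, -2.7, -2.4, -2.1), c(-5.3, -3.4, -2.9, -2.6, -2.3))
published_err_grid_m <- rbind(
  c(3.7, 5.5, 6.1, 6.3, 6.6), c(2, 3.9, 4.4, 4.7, 5),
  c(0.9, 2.7, 3.3, 3.6, 3.9), c(0.1, 1.9, 2.5, 2.7, 3),
  c(-0.5, 1.3, 1.8, 2.1, 2.4), c(-1, 0.8, 1.3, 1.6, 1.9),
  c(-1.4, 0.4, 0.9, 1.2, 1.5), c(-1.8, 0.1, 0.6, 0.9, 1.2),
  c(-2, -0.2, 0.3, 0.6, 0.9), c(-2.3, -0.4, 0.1, 0.4, 0.7),
  c(-2.5, -0.6, -0.1, 0.2, 0.5), c(-2.7, -0.8, -0.3, 0, 0.3))

# published model-comparison rows: index, model, K, AICc, LL
published_model_table <- data.frame(
  index = rep(c("SA", "OA", "FA", "Err"), each = 7),
  K = c(4, 5, 3, 4, 3, 4, 3,
        3, 4, 4, 5, 3, 4, 3,
        4, 3, 5, 4, 3, 4, 3,
        5, 4, 4, 3, 4, 3, 3),
  AICc = c(4616.249, 4618.245, 4638.388, 4640.41, 4681.157, 4683.142, 4763.543,
           5031.837, 5033.305, 5033.721, 5035.21, 5052.412, 5054.423, 5054.875,
           4750.881, 4750.967, 4751.845, 4752.079, 4756.205, 4756.308, 4758.718,
           4021.139, 4024.424, 4031.78, 4034.46, 4041.586, 4050.334, 4058.436),
  LL = c(-2304.09, -2304.07, -2316.17, -2316.17, -2337.56, -2337.53, -2378.75,
         -2512.9, -2512.62, -2512.82, -2512.55, -2523.18, -2523.17, -2524.42,
         -2371.4, -2372.46, -2370.87, -2372, -2375.08, -2374.12, -2376.34,
         -2005.51, -2008.18, -2011.85, -2014.21, -2016.76, -2022.14, -2026.2))

# tolerance limits (ITL, OTL) and the published percentile grids
published_limits <- list(SA = c(90.0, 97.4), OA = c(86.1, 98.8),
                         FA = c(41.0, 49.2), Err = c(29.9, 35.2))

# one participant's four cards as long-format rows
make_cards <- function(id = "P1", age = 40, edu = 13, gender = "F",
                       times, om = c(0, 0, 0, 0), sub = c(0, 0, 0, 0),
                       auto = c(0, 0, 0, 0)) {
  data.frame(participant_id = id, age_years = age, education_years = edu,
             gender = gender, card = 1:4, execution_time_s = times,
             omissions = om, substitutions = sub, autocorrections = auto,
             stringsAsFactors = FALSE)
}
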