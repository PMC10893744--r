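# small builders shared across tests

make_ct <- function(years = 2023:2025,
                    cells = rbind(c(200, 300, 500),
                                  c(210, 310, 520),
                                  c(220, 320, 540)),
                    totals = NULL, scenario = NULL) {
  df <- data.frame(year = rep(years, each = 3L),
                   stage = rep(pc_stages(), times = length(years)),
                   cases = as.vector(t(cells)))
  case_table(df, year_totals = if (is.null(totals)) NULL
             else stats::setNames(totals, years),
             scenario = scenario)
}

# published Victorian 2023-2027 case tables, as printed (year x stage)
printed_status_quo <- rbind(
  `2023` = c(198, 297, 495), `2024` = c(206, 308, 514),
  `2025` = c(210, 315, 526), `2026` = c(215, 323, 538),
  `2027` = c(220, 330, 550))
printed_scenarios <- list(
  "20% stage-IV reduction" = rbind(
    `2023` = c(351, 244, 396), `2024` = c(364, 253, 411),
    `2025` = c(372, 259, 420), `2026` = c(381, 265, 430),
    `2027` = c(390, 271, 440)),
  "50% stage-IV reduction" = rbind(
    `2023` = c(499, 244, 248), `2024` = c(518, 253, 257),
    `2025` = c(530, 259, 263), `2026` = c(542, 265, 269),
    `2027` = c(555, 271, 275)),
  "70% stage-IV reduction (base case)" = rbind(
    `2023` = c(598, 244, 149), `2024` = c(621, 253, 154),
    `2025` = c(635, 259, 158), `2026` = c(649, 265, 161),
    `2027` = c(665, 271, 165)))
printed_totals <- c(`2023` = 991, `2024` = 1028, `2025` = 1051,
                    `2026` = 1075, `2027` = 1100)

fixture_rates <- survival_rates(c(0.416, 0.144, 0.030))
fixture_shares <- stage_distribution(c(0.20, 0.30, 0.50))
fixture_bands <- remoteness_shares(c(0.81, 0.0575, 0.06, 0.0725))

# independent least-squares oracle for the log-linear slope (closed form,
# never via lm or the package's fitter)
ols_log_slope <- function(year, count, offset = 0) {
  x <- year - mean(year)
  y <- log(count + offset)
  sum(x * (y - mean(y))) / sum(x^2)
}
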