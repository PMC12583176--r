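#' Published Sanming reference tables
#'
#' The published point estimates of the Sanming reform evaluation, shipped
#' as plain-text data: the covariate balance table (predictor importance V,
#' treated and synthetic predictor values, reported percent bias) and the
#' post-treatment per-year effects (actual, synthetic, effect). These are
#' inputs for arithmetic self-consistency checks — the underlying 204-city
#' panel is not publicly deposited, so the package's estimators are
#' validated on synthetic data while the reported arithmetic (gaps, means,
#' percent bias) is verified directly against these printed columns. The
#' printed summary row of the effects table is `c(actual = 0.369,
#' synthetic = 0.5102, effect = -0.1412)`, attached as attribute
#' `published_means`.
#'
#' @return list with data.frames `balance` and `effects`.
#' @export
sanming_tables <- function() {
  dir <- system.file("extdata", package = "healthscm")
  balance <- utils::read.csv(file.path(dir, "sanming_balance_published.csv"),
                             stringsAsFactors = FALSE)
  effects <- utils::read.csv(file.path(dir, "sanming_effects_published.csv"),
                             stringsAsFactors = FALSE)
  attr(effects, "published_means") <-
    c(actual = 0.369, synthetic = 0.5102, effect = -0.1412)
  list(balance = balance, effects = effects)
}
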