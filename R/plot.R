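#' Score-hazard association curve with spline comparison
#'
#' Plots the covariate-adjusted log hazard ratio against the composite
#' score, from the linear-term model and from the restricted-cubic-spline
#' model (3 knots at the 10th/50th/90th percentiles), both centred at the
#' median score. Requires ggplot2.
#'
#' @param records data.frame with outcome, score and covariates.
#' @param score Score column name.
#' @param covariates Covariate design columns.
#' @param gridLength Number of score values to evaluate.
#' @return A ggplot object.
#' @export
plotScoreHazard <- function(records, score, covariates = character(),
                            gridLength = 100L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  x <- records[[score]]
  knots <- unname(quantile(x, c(0.1, 0.5, 0.9)))
  rec <- records
  basis <- .rcsBasis(x, knots)
  nl <- sprintf("%s_rcs%d", score, seq_len(ncol(basis)))
  rec[nl] <- basis
  fitLin <- fitCoxModel(rec, c(covariates, score))
  fitSpl <- fitCoxModel(rec, c(covariates, score, nl))
  xs <- seq(min(x), max(x), length.out = gridLength)
  med <- stats::median(x)
  bLin <- fitLin$coef[[score]]
  bSpl <- c(fitSpl$coef[[score]], fitSpl$coef[nl])
  bas <- function(v) cbind(v, .rcsBasis(v, knots))
  df <- rbind(
    data.frame(score = xs, loghr = bLin * (xs - med), model = "linear"),
    data.frame(score = xs,
               loghr = drop((bas(xs) - rep(bas(med), each = gridLength)) %*% bSpl),
               model = "restricted cubic spline"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$loghr,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = data.frame(score = x, loghr = 0,
                                        model = "linear"),
                      sides = "b", alpha = 0.15) +
    ggplot2::labs(x = "composite score", y = "log hazard ratio",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
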