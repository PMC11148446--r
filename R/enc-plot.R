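# ENC-plot analysis: observed ENC against GC3s, compared with the expected
# curve under mutation pressure alone. Genes falling well below the curve
# point at selection shaping codon usage beyond mutational bias.

#' Expected ENC under mutation pressure alone
#'
#' The standard ENC-plot curve
#' `ENC = 2 + s + 29 / (s^2 + (1 - s)^2)` with `s` the GC3s value.
#'
#' @param gc3s Numeric vector of GC3s values in \[0, 1\].
#' @return Expected ENC at each `gc3s`; the curve peaks at 60.5 for
#'   `gc3s = 0.5` and equals 31 and 32 at the endpoints 0 and 1.
#' @examples
#' expected_enc(c(0, 0.5, 1))
#' @export
expected_enc <- function(gc3s) {
  if (any(!is.finite(gc3s)) || any(gc3s < 0) || any(gc3s > 1)) {
    stop("`gc3s` must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Per-gene deviation from the ENC-plot curve
#'
#' @param stats A `gene_codon_stats` table from [usage_table()] (needs
#'   columns `gene`, `ENC`, `GC3s`).
#' @param tolerance Half-width, in ENC units, of the "near the curve" band
#'   (default 2). The band is an explicit analysis parameter, not an
#'   estimate.
#' @return Data frame with columns `gene`, `GC3s`, `ENC_obs`, `ENC_exp`,
#'   `deviation` (observed minus expected) and `flag` (`"near"` when
#'   `|deviation| <= tolerance`, `"below"` when `deviation < -tolerance`,
#'   `"above"` otherwise). Genes with missing ENC or GC3s are dropped with
#'   a warning.
#' @export
enc_deviation <- function(stats, tolerance = 2) {
  stopifnot(is.data.frame(stats),
            all(c("gene", "ENC", "GC3s") %in% names(stats)),
            tolerance >= 0)
  ok <- !is.na(stats$ENC) & !is.na(stats$GC3s)
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " gene(s) with missing ENC/GC3s: ",
            paste(stats$gene[!ok], collapse = ", "))
  }
  stats <- stats[ok, , drop = FALSE]
  exp_enc <- if (nrow(stats) > 0L) expected_enc(stats$GC3s) else numeric(0)
  dev <- stats$ENC - exp_enc
  flag <- ifelse(abs(dev) <= tolerance, "near",
                 ifelse(dev < -tolerance, "below", "above"))
  out <- data.frame(
    gene = stats$gene, GC3s = stats$GC3s, ENC_obs = stats$ENC,
    ENC_exp = exp_enc, deviation = dev, flag = flag,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' ENC-plot figure
#'
#' Scatter of observed ENC against GC3s with the expected mutation-only
#' curve overlaid. Requires ggplot2; the TSV from [enc_deviation()] is the
#' primary, headless artifact.
#'
#' @param deviation Output of [enc_deviation()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_enc <- function(deviation, title = "ENC-plot") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; the TSV output is headless")
  }
  curve <- data.frame(GC3s = seq(0, 1, by = 0.005))
  curve$ENC <- expected_enc(curve$GC3s)
  ggplot2::ggplot(deviation, ggplot2::aes(x = GC3s, y = ENC_obs)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = GC3s, y = ENC),
                       linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = flag)) +
    ggplot2::labs(x = "GC3s", y = "ENC", title = title) +
    ggplot2::ylim(0, 65) +
    ggplot2::theme_bw()
}
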