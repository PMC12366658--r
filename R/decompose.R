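#' Decompose quartets of trait values into intrinsic, extrinsic and
#' interaction divergence
#'
#' The central estimator of the package. Each trait (usually a gene in one
#' cell type) is measured in the four species-environment combinations of a
#' pair of reciprocal mouse-rat chimeras: host mouse (`HM`, mouse cells in a
#' mouse-like environment), host rat (`HR`, rat cells in a rat-like
#' environment), donor mouse (`DM`, mouse cells in a rat-like environment)
#' and donor rat (`DR`, rat cells in a mouse-like environment). Modelling
#' each measurement as the product of an intrinsic (genotype) factor and an
#' extrinsic (environment) factor gives two independent estimates of the
#' intrinsic divergence and two of the extrinsic divergence:
#'
#' \deqn{I_1 = \log_2(HR/DM), \quad I_2 = \log_2(DR/HM)}
#' \deqn{E_1 = \log_2(DM/HM), \quad E_2 = \log_2(HR/DR)}
#'
#' In the absence of noise and of any genotype-by-environment interaction the
#' paired estimates agree; their discrepancy estimates the interaction
#' divergence \eqn{N = (I_1 - I_2)/2 = (E_2 - E_1)/2}. The final estimates
#' are the averages \eqn{I = (I_1+I_2)/2} and \eqn{E = (E_1+E_2)/2}. Positive
#' `I` and `E` mean higher in rat (cells, resp. environment); positive `N`
#' means higher in species-matched than in species-mismatched combinations.
#'
#' Proportions are magnitudes normalized to sum to one,
#' \eqn{I_p = |I|/(|I|+|E|+|N|)} etc., and signed proportions multiply each
#' proportion by the sign of its component. Proportions are only reported
#' for traits with some evidence of divergence: an absolute log2 fold-change
#' above `min_abs_lfc` in at least one of the four comparisons
#' \eqn{I_1, I_2, E_1, E_2} (strictly greater). Traits failing this filter
#' keep their component estimates but carry `NA` proportions.
#'
#' This closed-form estimator is exactly the saturated two-factor
#' (species x environment) linear model on the 2x2 table of log2 values:
#' `I` is the species main effect, `E` the environment main effect and `N`
#' the interaction contrast.
#'
#' @param quartets a data frame or matrix with columns `HM`, `HR`, `DM`,
#'   `DR` (strictly positive), one row per trait, plus optionally `gene_id`
#'   (taken from row names otherwise); a single named vector of length 4 is
#'   also accepted.
#' @param min_abs_lfc divergence-evidence threshold on
#'   \eqn{\max(|I_1|,|I_2|,|E_1|,|E_2|)} (log2 units); default 0.5.
#' @param cell_type optional label stored alongside each row.
#'
#' @return An object of class `divergence_decomp`: a data frame with columns
#'   `gene_id`, `cell_type`, `I1`, `I2`, `E1`, `E2`, `I`, `E`, `N`, `Ip`,
#'   `Ep`, `Np`, `signed_Ip`, `signed_Ep`, `signed_Np`,
#'   `passed_divergence_filter`.
#'
#' @examples
#' # purely intrinsic: rat cells 4x higher in both environments
#' decompose_divergence(c(HM = 2, HR = 8, DM = 2, DR = 8))
#' # purely extrinsic: rat-like environment 4x higher for both genotypes
#' decompose_divergence(c(HM = 2, HR = 8, DM = 8, DR = 2))
#' @seealso [divergence_filter()], [summarize_components()]
#' @export
decompose_divergence <- function(quartets, min_abs_lfc = 0.5,
                                 cell_type = NA_character_) {
  q <- as_quartet_table(quartets)
  if (any(!is.finite(as.matrix(q[, c("HM", "HR", "DM", "DR")]))) ||
      any(q$HM <= 0 | q$HR <= 0 | q$DM <= 0 | q$DR <= 0))
    stop("all quartet values must be strictly positive and finite")
  if (anyDuplicated(q$gene_id))
    stop("duplicate gene ids in quartet table")

  I1 <- log2(q$HR / q$DM)
  I2 <- log2(q$DR / q$HM)
  E1 <- log2(q$DM / q$HM)
  E2 <- log2(q$HR / q$DR)
  I <- (I1 + I2) / 2
  E <- (E1 + E2) / 2
  N <- (I1 - I2) / 2

  denom <- abs(I) + abs(E) + abs(N)
  passed <- pmax(abs(I1), abs(I2), abs(E1), abs(E2)) > min_abs_lfc
  ok <- passed & denom > 0
  Ip <- ifelse(ok, abs(I) / denom, NA_real_)
  Ep <- ifelse(ok, abs(E) / denom, NA_real_)
  Np <- ifelse(ok, abs(N) / denom, NA_real_)

  res <- data.frame(
    gene_id = q$gene_id,
    cell_type = rep_len(cell_type, nrow(q)),
    I1 = I1, I2 = I2, E1 = E1, E2 = E2,
    I = I, E = E, N = N,
    Ip = Ip, Ep = Ep, Np = Np,
    signed_Ip = sign(I) * Ip,
    signed_Ep = sign(E) * Ep,
    signed_Np = sign(N) * Np,
    passed_divergence_filter = passed,
    stringsAsFactors = FALSE
  )
  attr(res, "min_abs_lfc") <- min_abs_lfc
  class(res) <- c("divergence_decomp", "data.frame")
  res
}

# Accepts vector / matrix / data.frame input and returns a canonical
# data.frame with gene_id, HM, HR, DM, DR.
as_quartet_table <- function(quartets) {
  if (is.numeric(quartets) && is.null(dim(quartets))) {
    if (!all(c("HM", "HR", "DM", "DR") %in% names(quartets)))
      stop("a quartet vector needs names HM, HR, DM, DR")
    quartets <- as.data.frame(as.list(quartets[c("HM", "HR", "DM", "DR")]))
  }
  q <- as.data.frame(quartets, stringsAsFactors = FALSE)
  missing <- setdiff(c("HM", "HR", "DM", "DR"), colnames(q))
  if (length(missing))
    stop("quartet table lacks columns: ", paste(missing, collapse = ", "))
  if (is.null(q$gene_id)) {
    q$gene_id <- if (!is.null(rownames(quartets)) &&
                     !identical(rownames(quartets),
                                as.character(seq_len(nrow(q)))))
      rownames(quartets)
    else
      sprintf("trait%04d", seq_len(nrow(q)))
  }
  rownames(q) <- NULL
  q[, c("gene_id", "HM", "HR", "DM", "DR")]
}

#' Divergence-evidence filter
#'
#' TRUE for quartets whose largest absolute log2 fold-change among the four
#' comparisons \eqn{I_1, I_2, E_1, E_2} exceeds `min_abs_lfc` (strictly).
#' Proportions are only interpretable for such traits.
#'
#' @inheritParams decompose_divergence
#' @return logical vector, one element per quartet.
#' @export
divergence_filter <- function(quartets, min_abs_lfc = 0.5) {
  q <- as_quartet_table(quartets)
  I1 <- log2(q$HR / q$DM); I2 <- log2(q$DR / q$HM)
  E1 <- log2(q$DM / q$HM); E2 <- log2(q$HR / q$DR)
  unname(pmax(abs(I1), abs(I2), abs(E1), abs(E2)) > min_abs_lfc)
}

#' @export
print.divergence_decomp <- function(x, ...) {
  cat(sprintf(
    "Divergence decomposition: %d trait(s), %d passing the divergence filter (|lfc| > %s)\n",
    nrow(x), sum(x$passed_divergence_filter), format(attr(x, "min_abs_lfc"))))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
summary.divergence_decomp <- function(object, ...) {
  keep <- object$passed_divergence_filter & !is.na(object$Ip)
  means <- if (any(keep)) {
    colMeans(object[keep, c("Ip", "Ep", "Np")])
  } else c(Ip = NA_real_, Ep = NA_real_, Np = NA_real_)
  out <- list(
    n = nrow(object),
    n_passed = sum(object$passed_divergence_filter),
    mean_proportions = means,
    component_quantiles = apply(object[, c("I", "E", "N")], 2,
                                stats::quantile, na.rm = TRUE)
  )
  class(out) <- "summary.divergence_decomp"
  out
}

#' @export
print.summary.divergence_decomp <- function(x, ...) {
  cat("Divergence decomposition summary\n")
  cat(sprintf("  traits: %d (%d pass divergence filter)\n", x$n, x$n_passed))
  cat(sprintf("  mean proportions (filter-passing): Ip=%.3f Ep=%.3f Np=%.3f\n",
              x$mean_proportions["Ip"], x$mean_proportions["Ep"],
              x$mean_proportions["Np"]))
  cat("  component quantiles (log2):\n")
  print(x$component_quantiles, digits = 3)
  invisible(x)
}

#' @export
coef.divergence_decomp <- function(object, ...) {
  m <- as.matrix(object[, c("I", "E", "N")])
  rownames(m) <- object$gene_id
  m
}

#' Scatterplot of signed intrinsic vs extrinsic proportions
#'
#' Filter-passing traits only; purely intrinsic traits lie on the x axis,
#' purely extrinsic on the y axis, and interaction-dominated traits near the
#' origin (point color encodes the interaction proportion).
#'
#' @param x a `divergence_decomp` object.
#' @param ... forwarded to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.divergence_decomp <- function(x, ...) {
  keep <- x$passed_divergence_filter & !is.na(x$signed_Ip)
  pal <- grDevices::colorRamp(c("grey60", "firebrick"))
  np <- x$Np[keep]
  col <- grDevices::rgb(pal(pmin(np, 1)), maxColorValue = 255)
  graphics::plot(x$signed_Ip[keep], x$signed_Ep[keep], col = col, pch = 16,
                 xlim = c(-1, 1), ylim = c(-1, 1),
                 xlab = "signed intrinsic proportion",
                 ylab = "signed extrinsic proportion", ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  invisible(x)
}

#' Write a decomposition table to TSV
#'
#' @param x a `divergence_decomp` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_decomposition <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
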