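# KZNF / TE-family anticorrelation screen by ranked correlation.

#' Pairwise Spearman correlation of TE families against KZNFs
#'
#' Computes Spearman's rho (mid-rank ties) for every (TE family, KZNF)
#' pair across the shared samples, a two-sided p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`, and BH
#' adjustment across the full pair grid.  Constant vectors yield NA rho
#' with a message reporting how many pairs were affected.
#'
#' @param family_expr families x samples matrix (typically log2(TPM+1)
#'   family means) or `abundance_matrix`.
#' @param kznf_expr KZNFs x samples matrix or `abundance_matrix`.
#' @return data.frame of class `correlation_result`: `te_family, kznf,
#'   rho, p, q, n`.
#' @export
spearman_matrix <- function(family_expr, kznf_expr) {
  fam <- .values(family_expr)
  kz <- .values(kznf_expr)
  shared <- intersect(colnames(fam), colnames(kz))
  n <- length(shared)
  if (n < 4) stop("need >= 4 shared samples", call. = FALSE)
  fam <- fam[, shared, drop = FALSE]
  kz <- kz[, shared, drop = FALSE]
  rho <- suppressWarnings(cor(t(fam), t(kz), method = "spearman"))
  n_na <- sum(is.na(rho))
  if (n_na > 0)
    message(n_na, " pair(s) with a constant vector reported as NA")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) == 1] <- 0
  out <- data.frame(te_family = rep(rownames(fam), times = ncol(rho)),
                    kznf = rep(colnames(rho), each = nrow(rho)),
                    rho = as.vector(rho), p = as.vector(p),
                    n = n, row.names = NULL)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], "BH")
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Screen for anticorrelated KZNF-TE family pairs
#'
#' Retains pairs with `rho <= rho_max` and `q <= q_max`, sorted by rho
#' ascending (strongest anticorrelation first).  When a list of known
#' repressor-target pairs is supplied (e.g. ChIP-exo-confirmed bindings),
#' reports which of them the screen recovers.
#'
#' @param results a [spearman_matrix()] result.
#' @param rho_max correlation ceiling (default -0.3).
#' @param q_max BH-adjusted p ceiling (default 0.05).
#' @param known_pairs optional data.frame with columns `kznf, te_family`.
#' @return list of class `anticorr_screen` with `screen` (filtered,
#'   sorted pair table) and `recovery` (known pairs with a `recovered`
#'   flag, or NULL).
#' @export
anticorrelation_screen <- function(results, rho_max = -0.3, q_max = 0.05,
                                   known_pairs = NULL) {
  keep <- !is.na(results$rho) & !is.na(results$q) &
    results$rho <= rho_max & results$q <= q_max
  screen <- results[keep, , drop = FALSE]
  screen <- screen[order(screen$rho), ]
  rownames(screen) <- NULL
  recovery <- NULL
  if (!is.null(known_pairs) && nrow(known_pairs)) {
    key <- paste(screen$kznf, screen$te_family, sep = "\r")
    recovery <- data.frame(known_pairs,
                           recovered = paste(known_pairs$kznf,
                                             known_pairs$te_family,
                                             sep = "\r") %in% key)
  }
  structure(list(screen = screen, recovery = recovery,
                 rho_max = rho_max, q_max = q_max),
            class = "anticorr_screen")
}

#' @export
print.anticorr_screen <- function(x, ...) {
  cat(sprintf("anticorr_screen: %d pair(s) at rho <= %g, q <= %g\n",
              nrow(x$screen), x$rho_max, x$q_max))
  if (nrow(x$screen)) print(utils::head(as.data.frame(x$screen), 10))
  if (!is.null(x$recovery))
    cat(sprintf("known pairs recovered: %d / %d\n",
                sum(x$recovery$recovered), nrow(x$recovery)))
  invisible(x)
}
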