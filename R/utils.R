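#' @keywords internal
"_PACKAGE"

## Seed fan-out: one user-facing seed, fixed offsets per component, so any
## stage can be reproduced in isolation. Offsets kept < 2^31 - seed range.
child_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

## delta-method scale factor: a shift of `d` on the beta scale around mean m
## corresponds to d / (m (1-m)) on the logit scale.
logit_scale <- function(d, m) d / (m * (1 - m))

#' Convert methylation beta values to M-values
#'
#' M = log2(beta / (1 - beta)). Values are clamped away from 0 and 1 by
#' `eps` before the transform.
#'
#' @param beta numeric vector or matrix of beta values in \[0, 1\].
#' @param eps clamp margin.
#' @return same shape as `beta`, on the M-value scale.
#' @export
beta2m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#' @param m numeric vector or matrix of M-values.
#' @return beta values in (0, 1).
#' @export
m2beta <- function(m) 2^m / (1 + 2^m)

## Global sample-alignment guard: every cross-matrix operation goes through
## this before any statistic is computed.
check_alignment <- function(..., what = "inputs") {
  ids <- list(...)
  ids <- ids[!vapply(ids, is.null, logical(1))]
  if (length(ids) < 2) return(invisible(TRUE))
  ref <- ids[[1]]
  for (i in seq_along(ids)[-1]) {
    if (length(ids[[i]]) != length(ref) || !all(ids[[i]] == ref)) {
      stop("sample identifiers are not aligned across ", what,
           "; refusing to compute statistics on misaligned matrices",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

## Build a full-rank design matrix from a covariate data frame, dropping
## collinear columns with a warning (documented rule: keep leftmost).
build_design <- function(covariates, extra = NULL) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    X <- matrix(1, nrow = if (is.null(extra)) 0 else nrow(extra), ncol = 1)
    colnames(X) <- "(Intercept)"
  } else {
    X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    X <- cbind(X, extra)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[(qx$rank + 1):ncol(X)]
    warning("dropping collinear design column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  X
}

## Residual maker: residuals of (vector or matrix) y on column space of X.
resid_on <- function(y, X) {
  qr.resid(qr(X), as.matrix(y))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
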