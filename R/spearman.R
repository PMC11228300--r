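# Spearman rank correlation with exact small-sample permutation p-values.
#
# With n = 5-6 animals per genotype the asymptotic p-value for Spearman's
# rho is unreliable, so for tie-free data with n <= 9 the two-sided p is
# computed from the exact permutation null (all n! rank arrangements,
# enumerated once per n and memoised). Ties or larger n fall back to the
# t approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df.

.cofos_cache <- new.env(parent = emptyenv())

.all_permutations <- function(n) {
  key <- paste0("perm", n)
  if (!is.null(.cofos_cache[[key]])) return(.cofos_cache[[key]])
  rec <- function(k) {
    if (k == 1L) return(matrix(1L, 1L, 1L))
    sub <- rec(k - 1L)
    m <- nrow(sub)
    out <- matrix(0L, k * m, k)
    for (i in seq_len(k)) {
      out[(i - 1L) * m + seq_len(m), ] <- cbind(i, sub + (sub >= i))
    }
    out
  }
  .cofos_cache[[key]] <- rec(as.integer(n))
  .cofos_cache[[key]]
}

# null distribution of rho over all n! tie-free rank arrangements
.spearman_null_rho <- function(n) {
  key <- paste0("null", n)
  if (!is.null(.cofos_cache[[key]])) return(.cofos_cache[[key]])
  P <- .all_permutations(n)
  S <- colSums((t(P) - seq_len(n))^2)
  .cofos_cache[[key]] <- 1 - 6 * S / (n * (n^2 - 1))
  .cofos_cache[[key]]
}

.spearman_p_exact <- function(rho, n) {
  null_abs <- abs(.spearman_null_rho(n))
  u <- unique(rho)
  pu <- vapply(u, function(r) {
    if (is.na(r)) return(NA_real_)
    mean(null_abs >= abs(r) - 1e-12)
  }, numeric(1))
  pu[match(rho, u)]
}

# t approximation: last-resort tail for tied data (cor.test does the
# same there)
.spearman_p_t <- function(rho, n) {
  r <- pmin(1, pmax(-1, rho))
  p <- rep(NA_real_, length(r))
  perfect <- !is.na(r) & abs(r) >= 1 - 1e-15
  p[perfect] <- 0
  ok <- !is.na(r) & !perfect
  tt <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

# does this R expose the Spearman null CDF routine used by cor.test?
.has_prho <- function() {
  if (is.null(.cofos_cache$has_prho)) {
    .cofos_cache$has_prho <- tryCatch({
      sym <- get("C_pRho", envir = asNamespace("stats"))
      abs(.Call(sym, 2, 5L, TRUE) - 1 / 120) < 1e-12  # P(S <= 0), n = 5
    }, error = function(e) FALSE)
  }
  .cofos_cache$has_prho
}

# tie-free p for n > 9 via the Edgeworth-corrected null distribution of
# S = sum(d^2) (AS 89), the same routine cor.test uses; the plain t
# approximation is anticonservative in the far tails at these n, which
# matters for FDR edge selection over ~2e4 region pairs
.spearman_p_edgeworth <- function(rho, n) {
  if (!.has_prho()) return(.spearman_p_t(rho, n))
  sym <- get("C_pRho", envir = asNamespace("stats"))
  mid <- (n^3 - n) / 6
  u <- unique(rho)
  pu <- vapply(u, function(r) {
    if (is.na(r)) return(NA_real_)
    s <- round((1 - r) * n * (n^2 - 1) / 6)
    p1 <- if (s > mid) .Call(sym, s, as.integer(n), FALSE)
          else .Call(sym, s + 2, as.integer(n), TRUE)
    min(1, max(0, 2 * p1))
  }, numeric(1))
  pu[match(rho, u)]
}

.spearman_p_approx <- function(rho, n, tie_free = TRUE) {
  if (tie_free && n > 9) .spearman_p_edgeworth(rho, n)
  else .spearman_p_t(rho, n)
}

#' Spearman rank correlation between two vectors
#'
#' Computes rho on average ranks (for tie-free data this equals the classic
#' closed form `1 - 6 * sum(d^2) / (n * (n^2 - 1))` with `d` the rank
#' differences). The two-sided p-value uses the exact permutation null over
#' all `n!` rank arrangements when the data are tie-free and `n <= 9`,
#' otherwise the t approximation.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return List with elements `rho`, `p`, `n`, `ties` (logical), `exact`
#'   (logical: exact permutation p used), `defined` (FALSE when either
#'   vector has zero variance, in which case `rho` and `p` are `NA`).
#' @examples
#' spearman_rho(1:6, c(1, 2, 3, 4, 6, 5))$rho  # 0.94285714
#' @export
spearman_rho <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, ties = NA,
                exact = FALSE, defined = FALSE))
  }
  rx <- rank(x)
  ry <- rank(y)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  rho <- stats::cor(rx, ry)
  exact <- !ties && n <= 9
  p <- if (exact) .spearman_p_exact(rho, n)
       else .spearman_p_approx(rho, n, tie_free = !ties)
  list(rho = rho, p = p, n = n, ties = ties, exact = exact, defined = TRUE)
}
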