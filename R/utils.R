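# Internal helpers shared across modules.

#' Geographical region codes
#'
#' The 13 region labels used throughout the package for sample metadata:
#' Eastern/Northern/Southern/Western Africa (AFE, AFN, AFS, AFW), the
#' Americas (AME), the Arabian Peninsula (ASA), Central-West/Eastern/
#' Southern Asia (ASC, ASE, ASS), Balkan Europe (EUB), Eastern Europe
#' (EUE), Italy (EUI) and Western Europe (EUW).
#'
#' @format Character vector of length 13.
#' @export
region_codes <- c("AFE", "AFN", "AFS", "AFW", "AME", "ASA", "ASC",
                  "ASE", "ASS", "EUB", "EUE", "EUI", "EUW")

# Error constructor: every user-facing failure carries a condition class
# of the form mthapnet_<class>_error so callers can branch on it.
mt_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("mthapnet_", class), "mthapnet_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map base characters to integer codes; anything outside A/C/G/T
# (N, IUPAC ambiguity, gaps) codes to 0 and is treated as missing.
.base_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_bases <- function(x) {
  # x: character matrix of single characters, or character vector of strings
  if (!is.matrix(x)) x <- do.call(rbind, strsplit(x, ""))
  m <- .base_codes[x]
  m[is.na(m)] <- 0L
  matrix(m, nrow = nrow(x), ncol = ncol(x), dimnames = dimnames(x))
}

# Weighted pairwise difference counts between rows of an integer code
# matrix; sites where either member codes 0 are skipped (pairwise
# deletion). Computed as (weighted both-valid sites) minus (weighted
# both-valid-and-equal sites), each a cross-product, so the cost is a
# handful of BLAS calls rather than an O(n^2 L) interpreted loop.
hamming_matrix <- function(codes, w = NULL) {
  n <- nrow(codes)
  L <- ncol(codes)
  if (is.null(w)) w <- rep(1, L)
  if (n < 1) return(matrix(0, 0, 0))
  valid <- (codes > 0L) * 1
  d <- tcrossprod(valid %*% diag(w, L), valid)
  for (b in 1:4) {
    ib <- (codes == b) * 1
    d <- d - tcrossprod(ib %*% diag(w, L), ib)
  }
  d[d < 0] <- 0  # floating-point dust
  diag(d) <- 0
  dimnames(d) <- list(rownames(codes), rownames(codes))
  d
}

# log(exp(a) + exp(b)) without overflow, vector-safe
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Resolve a per-position weight specification into a vector aligned with
# `positions`. `weights` may be NULL (all ones), an unnamed vector of
# length(positions), or a vector/list named by position.
resolve_weights <- function(weights, positions) {
  L <- length(positions)
  if (is.null(weights)) return(rep(1, L))
  if (is.null(names(weights))) {
    if (length(weights) != L)
      mt_stop("config", "unnamed weight vector must match the number of retained positions")
    w <- as.numeric(weights)
  } else {
    w <- rep(1, L)
    idx <- match(as.integer(names(weights)), positions)
    known <- !is.na(idx)
    w[idx[known]] <- as.numeric(weights)[known]
  }
  if (any(!is.finite(w)) || any(w <= 0))
    mt_stop("config", "position weights must be positive and finite")
  w
}
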