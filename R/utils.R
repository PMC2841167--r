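# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gm <- function(...) stop(sprintf(...), call. = FALSE)

#' Population standard deviation (n denominator)
#' @param x numeric vector
#' @return scalar SD with the n (not n-1) denominator
#' @keywords internal
#' @noRd
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# Cache of banded smoothing operators, keyed by "n|sigma|radius".
.gm_kernel_cache <- new.env(parent = emptyenv())

#' Banded 1D Gaussian convolution operator
#'
#' Returns an n x n matrix K with K[i, j] = g(j - i) for |j - i| <= radius,
#' where g is a unit-sum discrete Gaussian. Multiplying a signal by K performs
#' zero-padded convolution: mass beyond the border is simply lost, which is
#' the boundary rule used throughout the mapping pipeline.
#' @keywords internal
#' @noRd
gaussian_band <- function(n, sigma, radius = ceiling(4 * sigma)) {
  key <- paste(n, sigma, radius, sep = "|")
  hit <- .gm_kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - radius):min(n, i + radius)
    K[i, j] <- k[j - i + radius + 1L]
  }
  .gm_kernel_cache[[key]] <- K
  K
}

#' Zero-padded isotropic Gaussian blur of a matrix
#' @keywords internal
#' @noRd
gaussian_blur <- function(m, sigma) {
  Ky <- gaussian_band(nrow(m), sigma)
  Kx <- gaussian_band(ncol(m), sigma)
  Ky %*% m %*% t(Kx)
}

#' Label connected components of a logical mask (8-connectivity)
#'
#' @param mask logical matrix
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in decreasing size order
#' @keywords internal
#' @noRd
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0L) return(lab)
  pos <- integer(H * W)          # linear index -> vertex id
  pos[idx] <- seq_along(idx)
  row <- (idx - 1L) %% H + 1L
  col <- (idx - 1L) %/% H + 1L
  edges <- integer(0)
  # forward half of the 8-neighbourhood; backward pairs are implied
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + d[1L]; c2 <- col + d[2L]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- (c2[ok] - 1L) * H + r2[ok]
    hit <- pos[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(pos[idx[ok]][hit], pos[nb][hit]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  # renumber by decreasing size for stable output
  ord <- order(-tabulate(comp), sort(unique(comp)))
  renum <- integer(max(comp)); renum[ord] <- seq_along(ord)
  lab[idx] <- renum[comp]
  lab
}

#' Short stable hash of an R object (for config provenance)
#' @keywords internal
#' @noRd
config_hash <- function(x) rlang::hash(x)
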