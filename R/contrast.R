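# Contrast pathway: centre/surround luminance pooling (amacrine cells) and
# the T1 local-contrast signal, computed from the retina output.

# Box sum over a (2r+1)x(2r+1) window at every pixel, replicate padding,
# via an integral image. Oracle-checked against a direct double loop.
box_sum <- function(map, half) {
  nr <- nrow(map); nc <- ncol(map); r <- as.integer(half)
  padded <- map[c(rep(1L, r), seq_len(nr), rep(nr, r)),
                c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  cs <- apply(apply(padded, 2L, cumsum), 1L, cumsum)  # transposed integral
  sat <- matrix(0, nr + 2L * r + 1L, nc + 2L * r + 1L)
  sat[-1L, -1L] <- t(cs)
  side <- 2L * r + 1L
  hi_r <- seq_len(nr) + side; lo_r <- seq_len(nr)
  hi_c <- seq_len(nc) + side; lo_c <- seq_len(nc)
  sat[hi_r, hi_c] - sat[lo_r, hi_c] - sat[hi_r, lo_c] + sat[lo_r, lo_c]
}

#' Centre and surround luminance pools
#'
#' For every pixel, the total luminance over a centred `psi x psi` window
#' (the centre pool) and over the annulus between a `pi_win x pi_win`
#' window and the centre window (the surround pool). Window sides must be
#' odd with `pi_win > psi`. Borders use replicate padding so the pools are
#' defined at every pixel.
#'
#' @param P `H x W` matrix (one frame of the retina output).
#' @param psi Centre window side in pixels (default 11).
#' @param pi_win Outer window side in pixels (default 31).
#' @return List with matrices `cln` (centre pool) and `sln` (annulus pool).
#' @export
amc_pool <- function(P, psi = 11L, pi_win = 31L) {
  psi <- as.integer(psi); pi_win <- as.integer(pi_win)
  if (psi %% 2L == 0L || pi_win %% 2L == 0L) abort("window sides must be odd.")
  if (pi_win <= psi) abort("`pi_win` must be strictly larger than `psi`.")
  inner <- box_sum(P, (psi - 1L) %/% 2L)
  outer_ <- box_sum(P, (pi_win - 1L) %/% 2L)
  list(cln = inner, sln = outer_ - inner)
}

#' Local contrast from the centre/surround pools
#'
#' `T1 = SLN / (pi_win^2 - psi^2) - CLN / psi^2`: the mean luminance of the
#' surrounding annulus minus the mean of the centre window. Positive for a
#' dark feature on a brighter surround; exactly antisymmetric under
#' exchanging foreground and background luminances; zero on constant
#' frames.
#'
#' @param pools Output of [amc_pool()].
#' @param psi,pi_win The window sides the pools were computed with.
#' @return `H x W` matrix `T1` with `|T1| <= 255` for inputs in \[0, 255\].
#' @export
t1_contrast <- function(pools, psi = 11L, pi_win = 31L) {
  n_psi <- as.numeric(psi)^2
  n_ann <- as.numeric(pi_win)^2 - n_psi
  pools$sln / n_ann - pools$cln / n_psi
}

#' Local contrast of a full frame stack
#'
#' Applies [amc_pool()] and [t1_contrast()] to every frame of the retina
#' output; each frame is independent (no temporal filtering).
#'
#' @param P `H x W x T` array.
#' @inheritParams amc_pool
#' @return `H x W x T` array of `T1` local contrast.
#' @export
local_contrast <- function(P, psi = 11L, pi_win = 31L) {
  d <- dim(P)
  out <- array(0, dim = d)
  for (t in seq_len(d[3])) {
    out[, , t] <- t1_contrast(amc_pool(P[, , t], psi, pi_win), psi, pi_win)
  }
  out
}
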