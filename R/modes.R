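#' Render a phase-grating mode
#'
#' A probe mode is a linear phase grating `M(x, y) = 2*pi*(kx*x + ky*y) /
#' n_slm` (wrapped to `[0, 2*pi)`), with `x`, `y` the zero-based row and
#' column pixel indices of the SLM and `kx`, `ky` integer spatial
#' frequencies in cycles per aperture. Because the SLM is conjugate to
#' the pupil, displaying a grating translates the focal spot by exactly
#' `(kx, ky)` focal pixels (shift theorem), so the grating basis scans
#' the probe beam across the reference beam.
#'
#' @param kx,ky integer spatial frequencies.
#' @param n_slm SLM grid side.
#' @return `n_slm x n_slm` matrix of wrapped phases in `[0, 2*pi)`.
#' @examples
#' render_mode(1, 0, 8)[1:3, 1]
#' @export
render_mode <- function(kx, ky, n_slm) {
  x <- 0:(n_slm - 1L)
  (2 * pi * outer(kx * x, ky * x, "+") / n_slm) %% (2 * pi)
}

#' Build the grating mode basis
#'
#' Generates the `S x S` centred grid of integer frequency pairs
#' `(kx, ky)` with `kx, ky` in `[-floor(S/2), ...]` (for even `S` the
#' grid is `[-S/2, S/2 - 1]`). Under the default `spiral_low_to_high`
#' ordering, modes are sorted by increasing `kx^2 + ky^2` — low-order
#' aberrations are probed first — with ties broken deterministically by
#' polar angle and then `kx`; the zero-frequency mode `(0, 0)` comes
#' first. `raster` ordering enumerates the grid row by row.
#'
#' @param S side of the frequency grid; the basis holds `S^2` modes
#'   (e.g. `S = 15` gives the 225-mode basis, `S = 16` gives 256).
#' @param n_slm SLM grid side; must satisfy `S <= n_slm` to avoid
#'   aliasing.
#' @param ordering `"spiral_low_to_high"` or `"raster"`.
#' @return An object of class `"mode_basis"`: a list with `modes` (each a
#'   list with `n`, `kx`, `ky`, `pattern`, `unit` = `exp(1i * pattern)`),
#'   `n_modes`, `S`, `n_slm`, `ordering`.
#' @examples
#' b <- build_grating_basis(3, 8)
#' sapply(b$modes[1:5], function(m) c(m$kx, m$ky))
#' @export
build_grating_basis <- function(S, n_slm,
                                ordering = c("spiral_low_to_high",
                                             "raster")) {
  ordering <- match.arg(ordering)
  S <- as.integer(S); n_slm <- as.integer(n_slm)
  if (S > n_slm)
    stop("S (", S, ") exceeds n_slm (", n_slm, "): gratings would alias",
         call. = FALSE)
  if (S < 1L) stop("S must be >= 1", call. = FALSE)
  freqs <- seq.int(-(S %/% 2L), length.out = S)
  grid <- expand.grid(kx = freqs, ky = freqs)
  if (ordering == "spiral_low_to_high") {
    r2 <- grid$kx^2 + grid$ky^2
    ang <- atan2(grid$ky, grid$kx)
    grid <- grid[order(r2, ang, grid$kx), , drop = FALSE]
  }
  modes <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- render_mode(grid$kx[i], grid$ky[i], n_slm)
    modes[[i]] <- list(n = i - 1L, kx = grid$kx[i], ky = grid$ky[i],
                       pattern = p, unit = exp(1i * p))
  }
  structure(list(modes = modes, n_modes = length(modes), S = S,
                 n_slm = n_slm, ordering = ordering),
            class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf("<mode_basis> %d phase gratings (S = %d) on %d x %d SLM, %s\n",
              x$n_modes, x$S, x$n_slm, x$n_slm, x$ordering))
  invisible(x)
}

#' @export
as.data.frame.mode_basis <- function(x, ...) {
  data.frame(n = vapply(x$modes, `[[`, integer(1), "n"),
             kx = vapply(x$modes, `[[`, integer(1), "kx"),
             ky = vapply(x$modes, `[[`, integer(1), "ky"))
}
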