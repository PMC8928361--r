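# Coiflet-1 analysis filters (6 taps). The high-pass filter is the
# quadrature mirror of the low-pass: g[k] = (-1)^k h[m-1-k].
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
               0.3848648468648578,    0.8525720202116004,
               0.3378976624574818,   -0.07273261951252645)
COIF1_HI <- c( 0.07273261951252645,   0.3378976624574818,
              -0.8525720202116004,    0.3848648468648578,
               0.07273261951252645,  -0.015655728135791993)

# Circular (periodic) correlation of a 3D array with a short 1D filter
# along one axis, centered on tap ceil(m/2):
#   y[i] = sum_k f[k] * x[(i + k - center) mod n]
# Centering is a phase convention only; it commutes with circular shifts,
# which is what the translation-invariance property relies on.
filter_axis <- function(x, f, axis) {
  d <- dim(x)
  n <- d[axis]
  m <- length(f)
  if (n < m)
    af_stop("af_volume_too_small",
            "dimension %d (length %d) shorter than filter support %d",
            axis, n, m)
  centre <- ceiling(m / 2)
  y <- array(0, dim = d)
  base <- seq_len(n)
  for (k in seq_len(m)) {
    idx <- ((base + k - centre - 1L) %% n) + 1L
    y <- y + f[k] * switch(axis,
                           x[idx, , , drop = FALSE],
                           x[, idx, , drop = FALSE],
                           x[, , idx, drop = FALSE])
  }
  y
}

#' Stationary 3D wavelet subbands
#'
#' Single-level undecimated (stationary) 3D wavelet decomposition with the
#' coiflet-1 filter pair and periodic signal extension. The low (L) or high
#' (H) analysis filter is applied along each of the three axes in turn,
#' giving the eight subbands LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH (first
#' letter = axis 1). Because the transform is undecimated, every subband
#' keeps the original grid, so an atlas mask applies unchanged.
#'
#' @param volume a [brain_volume] (every dimension must be at least the
#'   filter length, 6).
#' @return named list of 8 [brain_volume] objects keyed `LLL` .. `HHH`.
#' @export
wavelet_subbands <- function(volume) {
  stopifnot(inherits(volume, "brain_volume"))
  x <- volume$data
  if (any(dim(x) < length(COIF1_LO)))
    af_stop("af_volume_too_small",
            "volume dimensions %s shorter than filter support %d",
            paste(dim(x), collapse = "x"), length(COIF1_LO))
  ax1 <- list(L = filter_axis(x, COIF1_LO, 1L), H = filter_axis(x, COIF1_HI, 1L))
  out <- vector("list", 8L)
  names(out) <- setdiff(SUBBANDS, "original")
  for (nm in names(out)) {
    code <- strsplit(nm, "")[[1]]
    y <- ax1[[code[1]]]
    y <- filter_axis(y, if (code[2] == "L") COIF1_LO else COIF1_HI, 2L)
    y <- filter_axis(y, if (code[3] == "L") COIF1_LO else COIF1_HI, 3L)
    out[[nm]] <- brain_volume(y, spacing = volume$spacing,
                              affine = volume$affine,
                              subject_id = volume$subject_id)
  }
  out
}
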