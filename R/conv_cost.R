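#' Multiply-add cost of standard vs depthwise-separable convolution
#'
#' For a square kernel of side \code{D_K}, \code{M} input channels, \code{N}
#' output channels and a square output map of side \code{D_F}:
#' standard convolution costs \code{Z_N = D_K^2 * M * N * D_F^2} multiply-adds,
#' the depthwise-separable factorization costs
#' \code{Z_S = D_K^2 * M * D_F^2 + M * N * D_F^2}, and their ratio reduces
#' exactly to \code{1/N + 1/D_K^2}.
#'
#' @param D_K Kernel side length.
#' @param M Input channels.
#' @param N Output channels.
#' @param D_F Output map side length.
#' @return List \code{Z_N}, \code{Z_S}, \code{ratio}.
#' @export
conv_cost <- function(D_K, M, N, D_F) {
  stopifnot(D_K >= 1, M >= 1, N >= 1, D_F >= 1)
  Z_N <- D_K^2 * M * N * D_F^2
  Z_S <- D_K^2 * M * D_F^2 + M * N * D_F^2
  list(Z_N = Z_N, Z_S = Z_S, ratio = Z_S / Z_N)
}
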