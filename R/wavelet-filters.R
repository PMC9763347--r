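# Orthonormal scaling filters (low-pass, synthesis order). Standard published
# coefficients for the Haar, Daubechies extremal-phase and least-asymmetric
# (Symmlet) families. The quadrature-mirror high-pass filter is derived as
# g[k] = (-1)^k h[L-1-k].

.pw_scaling_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
          -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
          0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953),
  db10 = c(0.026670057900555554, 0.1881768000776915, 0.5272011889317256,
           0.6884590394536035, 0.2811723436605775, -0.24984642432731538,
           -0.19594627437737705, 0.12736934033579325, 0.09305736460357235,
           -0.07139414716639708, -0.029457536821875813, 0.033212674059341,
           0.0036065535669561697, -0.010733175483330575, 0.001395351747052901,
           0.001992405295185056, -0.0006858566949597116,
           -0.00011646685512928545, 9.358867032006959e-05,
           -1.3264202894521244e-05),
  sym4 = c(0.0322231006040427, -0.012603967262037833, -0.09921954357684722,
           0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
           -0.02963552764599851, -0.07576571478927333),
  sym6 = c(-0.007800708325034148, 0.0017677118642428036, 0.04472490177066578,
           -0.021060292512300564, -0.07263752278646252, 0.3379294217276218,
           0.787641141030194, 0.4910559419267466, -0.048311742585633,
           -0.11799011114819057, 0.0034907120842174702, 0.015404109327027373),
  sym8 = c(0.0018899503327594609, -0.0003029205147213668, -0.01495225833704823,
           0.003808752013890615, 0.049137179673607506, -0.027219029917056003,
           -0.05194583810770904, 0.3644418948353314, 0.7771857517005235,
           0.4813596512583722, -0.061273359067658524, -0.1432942383508097,
           0.007607487324917605, 0.03169508781149298, -0.0005421323317911481,
           -0.0033824159510061256)
)

#' Orthonormal wavelet filter pair
#'
#' Returns the scaling (low-pass) and wavelet (high-pass) filters of a
#' supported orthogonal wavelet. The high-pass filter is the quadrature
#' mirror of the scaling filter.
#'
#' @param wavelet Wavelet name: one of `"haar"`, `"db2"`, `"db4"`, `"db6"`,
#'   `"db8"`, `"db10"`, `"sym4"`, `"sym6"`, `"sym8"`.
#'
#' @return A list with elements `h` (scaling filter), `g` (wavelet filter)
#'   and `wavelet` (the name).
#' @export
#'
#' @examples
#' wavelet_filter("haar")
wavelet_filter <- function(wavelet = "db6") {
  if (!is.character(wavelet) || length(wavelet) != 1 ||
      !wavelet %in% names(.pw_scaling_filters)) {
    abort(paste0(
      "`wavelet` must be one of: ",
      paste(names(.pw_scaling_filters), collapse = ", ")
    ), class = "pw_domain_error")
  }
  h <- .pw_scaling_filters[[wavelet]]
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * h[L:1]
  list(h = h, g = g, wavelet = wavelet)
}
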