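#' Standard 64-channel extended 10-20 layout
#'
#' An idealized extended 10-20 montage: 64 scalp electrodes plus
#' vertical and horizontal EOG. Positions are generated from idealized
#' spherical coordinates (anterior-posterior arc angle by row,
#' lateral arc angle by electrode number) and azimuthally projected into
#' the unit disk (x to the right, y anterior). The exact cap geometry of
#' any particular amplifier is not reproduced; what matters downstream
#' is a plausible, fixed 2-D geometry containing the standard labels.
#'
#' @return a [ChannelLayout-class] with 66 channels (64 EEG + vEOG/hEOG).
#' @examples
#' lay <- standardLayout64()
#' head(channelPositions(lay))
#' @export
standardLayout64 <- function() {
  rowAngle <- c(Fp = 72, AF = 54, F = 36, FC = 18, FT = 18, C = 0, T = 0,
                CP = -18, TP = -18, P = -36, PO = -54, O = -72, I = -90)
  rows <- list(
    Fp = c("Fp1", "Fpz", "Fp2"),
    AF = c("AF7", "AF3", "AFz", "AF4", "AF8"),
    F  = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    FC = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
    C  = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
    CP = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
    P  = c("P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10"),
    PO = c("PO7", "PO3", "POz", "PO4", "PO8"),
    O  = c("O1", "Oz", "O2"),
    I  = c("Iz"))
  lateralOf <- function(name) {
    num <- sub("^[A-Za-z]+", "", name)
    if (num == "z" || num == "") return(c(0, 0))
    k <- as.integer(num)
    side <- if (k %% 2 == 1) -1 else 1       # odd left, even right
    c(side, min(90, ceiling(k / 2) * 18))
  }
  nm <- character(0); px <- numeric(0); py <- numeric(0)
  for (r in names(rows)) {
    a <- rowAngle[[r]] * pi / 180
    for (ch in rows[[r]]) {
      sl <- lateralOf(ch)
      l <- sl[1] * sl[2] * pi / 180
      # vertex z-axis; rotate anterior by a, lateral by l
      v <- c(cos(a) * sin(l), sin(a), cos(a) * cos(l))
      theta <- acos(pmin(1, pmax(-1, v[3])))
      r2d <- 0.82 * theta / (pi / 2)
      hyp <- sqrt(v[1]^2 + v[2]^2)
      if (hyp < 1e-12) {
        xy <- c(0, 0)
      } else {
        xy <- r2d * c(v[1], v[2]) / hyp
      }
      nm <- c(nm, ch); px <- c(px, xy[1]); py <- c(py, xy[2])
    }
  }
  nm <- c(nm, "vEOG", "hEOG")
  px <- c(px, 0.15, 1.05)
  py <- c(py, 1.05, 0.30)
  new("ChannelLayout", names = nm,
      pos2d = cbind(px, py),
      type = c(rep("eeg", 64L), "eog", "eog"))
}
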