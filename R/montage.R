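# Idealized spherical 64-channel 10-10 montage.
#
# The head is a unit sphere: x toward the right preauricular point,
# y toward the nasion, z toward the vertex. The outer (equatorial) ring
# runs Fpz .. T7 .. Oz .. T8 at 18-degree azimuth steps; midline and
# coronal chains step 22.5 degrees in inclination; the remaining
# electrodes lie on great-circle arcs between their equatorial and
# midline anchors (the usual idealization of the 10-10 layout).

slerp <- function(p0, p1, t) {
  om <- acos(max(-1, min(1, sum(p0 * p1))))
  if (om < 1e-12) return(p0)
  (sin((1 - t) * om) * p0 + sin(t * om) * p1) / sin(om)
}

equator_point <- function(az_deg) {
  a <- az_deg * pi / 180 # 0 = front, positive to the left
  c(x = -sin(a), y = cos(a), z = 0)
}

midline_point <- function(incl_deg, front = TRUE) {
  b <- incl_deg * pi / 180
  c(x = 0, y = if (front) sin(b) else -sin(b), z = cos(b))
}

#' Standard 64-channel scalp montage plus EOG channels
#'
#' Returns an idealized unit-sphere 10-10 montage of 64 scalp electrodes
#' (including mastoids M1/M2 and the full peri-occipital set O1, O2, Oz,
#' POz, PO3-PO8 used for pooling) together with four EOG channels (no
#' scalp coordinates).
#'
#' @return data.frame of class `fg_montage` with columns `label`, `x`,
#'   `y`, `z`, `type` (`"scalp"` or `"eog"`).
#' @export
standard_montage <- function() {
  pos <- list()
  add <- function(label, p) pos[[label]] <<- p

  # equatorial ring (inclination 90), azimuth from front midline
  eq <- c(Fpz = 0, Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
          TP7 = 108, P7 = 126, PO7 = 144, O1 = 162, Oz = 180)
  for (l in names(eq)) add(l, equator_point(eq[[l]]))
  eq_r <- c(Fp2 = -18, AF8 = -36, F8 = -54, FT8 = -72, T8 = -90,
            TP8 = -108, P8 = -126, PO8 = -144, O2 = -162)
  for (l in names(eq_r)) add(l, equator_point(eq_r[[l]]))

  # midline chain
  add("AFz", midline_point(67.5)) # anchor only, dropped below
  add("Fz",  midline_point(45))
  add("FCz", midline_point(22.5))
  add("Cz",  c(x = 0, y = 0, z = 1))
  add("CPz", midline_point(22.5, front = FALSE))
  add("Pz",  midline_point(45, front = FALSE))
  add("POz", midline_point(67.5, front = FALSE))

  # lateral rows: arc from the equatorial anchor to the midline anchor
  row_arc <- function(anchor_eq, anchor_mid, labels, fracs) {
    for (i in seq_along(labels)) {
      lab <- labels[i]
      add(lab, slerp(pos[[anchor_eq]], pos[[anchor_mid]], fracs[i]))
    }
  }
  row_arc("AF7", "AFz", "AF3", 0.5)
  row_arc("F7", "Fz", c("F5", "F3", "F1"), c(0.25, 0.5, 0.75))
  row_arc("FT7", "FCz", c("FC5", "FC3", "FC1"), c(0.25, 0.5, 0.75))
  row_arc("T7", "Cz", c("C5", "C3", "C1"), c(0.25, 0.5, 0.75))
  row_arc("TP7", "CPz", c("CP5", "CP3", "CP1"), c(0.25, 0.5, 0.75))
  row_arc("P7", "Pz", c("P5", "P3", "P1"), c(0.25, 0.5, 0.75))
  row_arc("PO7", "POz", c("PO5", "PO3"), c(1 / 3, 2 / 3))
  # right hemisphere mirrors (negate x)
  mirror <- list(AF4 = "AF3", F2 = "F1", F4 = "F3", F6 = "F5",
                 FC2 = "FC1", FC4 = "FC3", FC6 = "FC5",
                 C2 = "C1", C4 = "C3", C6 = "C5",
                 CP2 = "CP1", CP4 = "CP3", CP6 = "CP5",
                 P2 = "P1", P4 = "P3", P6 = "P5",
                 PO4 = "PO3", PO6 = "PO5")
  for (l in names(mirror)) {
    p <- pos[[mirror[[l]]]]
    add(l, c(x = -p[["x"]], y = p[["y"]], z = p[["z"]]))
  }
  # mastoids: below the equator behind the ears
  b <- 100 * pi / 180; a <- 110 * pi / 180
  add("M1", c(x = -sin(b) * sin(a), y = sin(b) * cos(a), z = cos(b)))
  add("M2", c(x = sin(b) * sin(a), y = sin(b) * cos(a), z = cos(b)))

  pos[["AFz"]] <- NULL # anchor not part of the 64-channel cap
  labs <- names(pos)
  m <- do.call(rbind, pos)
  m <- m / sqrt(rowSums(m^2)) # exact unit norm
  out <- data.frame(label = labs, x = m[, 1], y = m[, 2], z = m[, 3],
                    type = "scalp", stringsAsFactors = FALSE)
  eog <- data.frame(label = c("VEOG1", "VEOG2", "HEOG1", "HEOG2"),
                    x = NA_real_, y = NA_real_, z = NA_real_, type = "eog",
                    stringsAsFactors = FALSE)
  out <- rbind(out, eog)
  rownames(out) <- NULL
  class(out) <- c("fg_montage", "data.frame")
  out
}

#' Peri-occipital electrode pool
#'
#' The a-priori pooling used for all ERP analyses.
#'
#' @return character vector of 10 channel labels.
#' @export
pool_channels <- function() {
  c("O1", "O2", "Oz", "POz", "PO3", "PO4", "PO5", "PO6", "PO7", "PO8")
}

scalp_labels <- function(montage) montage$label[montage$type == "scalp"]
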