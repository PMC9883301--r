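# Peak definitions and peak lists.
#
# A peak list is an ordered tibble of mass-peak definitions shared by the
# synthetic generator, the event-stream reader and every analysis stage.
# Columns:
#   label         unique peak name, e.g. "H25O12+" or "mz332.14"
#   center_mz     peak centre (u)
#   window_lo_mz  integration window, half-open [lo, hi)
#   window_hi_mz
#   assignment    chemical assignment (free text)
#   species       generator role: water / organic / salt_K / salt_Na /
#                 salt_Ca / substrate_Al / cipro / background (optional for
#                 lists produced by peak search, where it is "unknown")

PROTON_MASS <- 1.007276466
WATER_MASS <- 18.0105646863

#' Construct and validate a peak list
#'
#' @param label Character vector of unique peak labels.
#' @param center_mz Numeric peak centres (u), strictly increasing after
#'   ordering.
#' @param window_lo_mz,window_hi_mz Integration windows, half-open
#'   `[lo, hi)`; must bracket the centre and must not overlap between peaks.
#' @param assignment Chemical assignment strings.
#' @param species Generator role labels; defaults to `"unknown"`.
#' @return A tibble with one row per peak, ordered by `center_mz`.
#' @export
peaklist <- function(label, center_mz, window_lo_mz, window_hi_mz,
                     assignment = label, species = "unknown") {
  pl <- tibble::tibble(
    label = as.character(label),
    center_mz = as.numeric(center_mz),
    window_lo_mz = as.numeric(window_lo_mz),
    window_hi_mz = as.numeric(window_hi_mz),
    assignment = as.character(assignment),
    species = rep_len(as.character(species), length(label))
  )
  pl <- dplyr::arrange(pl, .data$center_mz)
  validate_peaklist(pl)
  pl
}

validate_peaklist <- function(pl) {
  req <- c("label", "center_mz", "window_lo_mz", "window_hi_mz")
  if (!all(req %in% names(pl))) {
    abort(paste0("peak list must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(pl$label)) abort("peak labels must be unique")
  if (is.unsorted(pl$center_mz, strictly = TRUE)) {
    abort("peak centres must be strictly increasing")
  }
  if (any(pl$window_lo_mz >= pl$center_mz | pl$window_hi_mz <= pl$center_mz)) {
    abort("each window must satisfy lo < center < hi")
  }
  n <- nrow(pl)
  if (n > 1 && any(pl$window_hi_mz[-n] > pl$window_lo_mz[-1] + 1e-12)) {
    abort("integration windows of distinct peaks must not overlap")
  }
  invisible(pl)
}

# Shrink default windows so neighbouring peaks never overlap; half the gap to
# the nearest neighbour, capped at `half_width`.
auto_windows <- function(center_mz, half_width = 0.015, min_half = 1e-4) {
  n <- length(center_mz)
  gap_lo <- c(Inf, diff(center_mz)) / 2
  gap_hi <- c(diff(center_mz), Inf) / 2
  lo <- center_mz - pmax(pmin(half_width, gap_lo - 1e-4), min_half)
  hi <- center_mz + pmax(pmin(half_width, gap_hi - 1e-4), min_half)
  list(lo = lo, hi = hi)
}

#' m/z values of the protonated water cluster series
#'
#' Masses of the \eqn{H_{2n+1}O_n^+} cluster ions that dominate positive-ion
#' spectra of frozen-hydrated samples: \eqn{m/z(n) = n \cdot m(H_2O) + m(H^+)}.
#'
#' @param n Integer cluster sizes.
#' @return Numeric m/z values.
#' @export
#' @examples
#' water_cluster_mz(c(12, 18)) # H25O12+ and H37O18+
water_cluster_mz <- function(n) {
  stopifnot(all(n >= 1))
  n * WATER_MASS + PROTON_MASS
}

#' Characteristic biofilm organic ions
#'
#' The organic fragment ions characteristic of gram-positive biofilm cells
#' (amino-acid, nucleobase, lipid head-group and cell-wall sugar fragments)
#' used by the synthetic generator and as biofilm markers in depth-profile
#' labelling.
#'
#' @return A tibble with columns `assignment`, `source`, `center_mz`.
#' @export
biofilm_organic_ions <- function() {
  tibble::tribble(
    ~assignment, ~source, ~center_mz,
    "CH4N+", "glycine (protein)", 30.03,
    "C2H6N+", "alanine (PE lipid head group fragment)", 44.05,
    "C3H4NO+", "asparagine", 70.05,
    "C4H8N+", "gram-positive bacteria, proline", 70.07,
    "C4H6NO+", "glutamic acid", 84.04,
    "C5H10N+", "lysine", 84.08,
    "C5H12N+", "PC lipid headgroup fragment", 86.10,
    "C4H5N3OH+", "cytosine", 112.05,
    "C5H5N5H+", "adenine", 136.06,
    "C5H5N5OH+", "guanine", 152.05,
    "C8H16NO6+", "N-acetyl-glucosamine", 222.10,
    "C11H20NO8+", "N-acetylmuramic acid", 294.12
  )
}

#' m/z of the protonated ciprofloxacin molecular ion
#' @return The (M+H)+ m/z, 332.14.
#' @export
cipro_mz <- function() 332.1405

#' Default peak list for synthetic biofilm cubes
#'
#' Builds the standard peak list used throughout the package: the water
#' cluster series \eqn{H_{2n+1}O_n^+} (n = 1..`n_water`), the characteristic
#' biofilm organic ions, the viability salts K+/Na+/Ca+, the Al+ substrate
#' ion, the ciprofloxacin (M+H)+ ion at m/z 332.14, and `n_background`
#' low-intensity background channels spread over the mass range (emulating
#' the long tail of minor peaks an automated peak search returns on real
#' spectra).
#'
#' @param n_water Largest water cluster size retained (default 20).
#' @param n_background Number of filler background channels (default 163,
#'   giving a 200-peak list with the named ions).
#' @return A peak-list tibble (see [peaklist()]).
#' @export
#' @examples
#' nrow(default_peaklist()) # 200
default_peaklist <- function(n_water = 20, n_background = 163) {
  named <- tibble::tibble(
    label = c(
      paste0("H", 2 * seq_len(n_water) + 1, "O", seq_len(n_water), "+"),
      biofilm_organic_ions()$assignment,
      "K+", "Na+", "Ca+", "Al+", "cipro"
    ),
    center_mz = c(
      water_cluster_mz(seq_len(n_water)),
      biofilm_organic_ions()$center_mz,
      38.9637, 22.9898, 39.9626, 26.9815, cipro_mz()
    ),
    assignment = c(
      paste0("H", 2 * seq_len(n_water) + 1, "O", seq_len(n_water), "+"),
      biofilm_organic_ions()$assignment,
      "K+", "Na+", "Ca+", "Al+", "cipro (M+H)+"
    ),
    species = c(
      rep("water", n_water),
      rep("organic", nrow(biofilm_organic_ions())),
      "salt_K", "salt_Na", "salt_Ca", "substrate_Al", "cipro"
    )
  )
  if (n_background > 0) {
    bg_mz <- seq(20.55, 348.05, length.out = n_background)
    # nudge any background channel that falls within 0.1 u of a named peak
    for (i in seq_along(bg_mz)) {
      while (any(abs(bg_mz[i] - named$center_mz) < 0.1)) bg_mz[i] <- bg_mz[i] + 0.11
    }
    named <- dplyr::bind_rows(named, tibble::tibble(
      label = sprintf("bg%03d", seq_len(n_background)),
      center_mz = bg_mz,
      assignment = "background",
      species = "background"
    ))
  }
  named <- dplyr::arrange(named, .data$center_mz)
  w <- auto_windows(named$center_mz)
  peaklist(named$label, named$center_mz, w$lo, w$hi,
           assignment = named$assignment, species = named$species)
}

#' Look up peak indices by label
#'
#' @param pl Peak-list tibble.
#' @param labels Character labels to find.
#' @return Integer positions in the peak list; errors if any label is absent.
#' @export
peak_index <- function(pl, labels) {
  idx <- match(labels, pl$label)
  if (anyNA(idx)) {
    abort(paste0("peaks not found in peak list: ",
                 paste(labels[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Write / read a peak list as tab-separated text
#'
#' @param pl Peak-list tibble.
#' @param path File path.
#' @return `read_peaklist()` returns the peak-list tibble.
#' @export
write_peaklist <- function(pl, path) {
  validate_peaklist(pl)
  write.table(pl, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path) {
  df <- tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  validate_peaklist(df)
  df
}
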