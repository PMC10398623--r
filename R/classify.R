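#' Van Krevelen / Kroll descriptors for a molecular formula
#'
#' Computes O/C, H/C, carbon number, the average carbon oxidation state
#' `OS_C = 2*O/C - H/C`, the Van Krevelen region and whether the
#' compound lies in the oxygenated-organic-aerosol oxidation-state band.
#' Region rules (strict inequalities; boundary cases fall outside):
#' aromatic when H/C < 1; OOA when 1.2 < H/C < 1.9 and 0.3 < O/C < 1;
#' otherwise "other". The Kroll band -1 < OS_C < 0.5 spans semi-volatile
#' and low-volatility oxygenated organic aerosol.
#'
#' @param f A `molform` object or formula string with at least one carbon.
#' @return List with `o_c`, `h_c`, `n_c`, `os_c`, `vk_region`,
#'   `kroll_band`.
#' @export
#' @examples
#' classify_compound("C5H8O3")  # levulinic acid: OS_C = -0.4, in band
classify_compound <- function(f) {
  r <- elemental_ratios(f)
  os_c <- 2 * r$o_c - r$h_c
  vk <- if (r$h_c < 1) {
    "aromatic"
  } else if (r$h_c > 1.2 && r$h_c < 1.9 && r$o_c > 0.3 && r$o_c < 1) {
    "OOA"
  } else {
    "other"
  }
  list(o_c = r$o_c, h_c = r$h_c, n_c = r$n_c, os_c = os_c,
       vk_region = vk, kroll_band = os_c > -1 && os_c < 0.5)
}

# colors used in the overview panels: CHO green, CHNO violet, rest light blue
.class_color <- function(class) {
  c(CHO = "#1b9e77", CHNO = "#7570b3", CHOS = "#d95f02",
    other = "#74add1")[class]
}

#' Plot-ready coordinate tables for the untargeted overview panels
#'
#' Builds the four standard untargeted-screening diagrams as plain
#' tables: m/z vs retention time, Van Krevelen (H/C vs O/C), Kroll
#' (OS_C vs carbon number) and the Kendrick plot (KMD vs KM). Marker
#' sizes scale with the square root of peak area; classes carry a fixed
#' color key. The Kendrick table is restricted to CHO compounds above an
#' area threshold.
#'
#' @param annotations Output of [annotate_features()] (columns `id`,
#'   `mz`, `rt`, `area`, `formula`, `class`).
#' @param kendrick_area_min Minimum area for the Kendrick panel
#'   (default 5e6).
#' @return List of data frames `mz_rt`, `van_krevelen`, `kroll`,
#'   `kendrick`.
#' @export
diagram_tables <- function(annotations, kendrick_area_min = 5e6) {
  stopifnot(is.data.frame(annotations), nrow(annotations) > 0)
  a <- annotations
  size <- sqrt(a$area / max(a$area, 1))
  mz_rt <- data.frame(id = a$id, mz = a$mz, rt = a$rt, area = a$area,
                      class = a$class, size = size,
                      color = unname(.class_color(a$class)),
                      stringsAsFactors = FALSE)
  with_formula <- !is.na(a$formula)
  desc <- lapply(a$formula[with_formula], classify_compound)
  vk <- data.frame(
    id = a$id[with_formula],
    o_c = vapply(desc, `[[`, numeric(1), "o_c"),
    h_c = vapply(desc, `[[`, numeric(1), "h_c"),
    vk_region = vapply(desc, `[[`, character(1), "vk_region"),
    area = a$area[with_formula], class = a$class[with_formula],
    size = size[with_formula],
    color = unname(.class_color(a$class[with_formula])),
    stringsAsFactors = FALSE
  )
  kroll <- data.frame(
    id = a$id[with_formula],
    n_c = vapply(desc, `[[`, numeric(1), "n_c"),
    os_c = vapply(desc, `[[`, numeric(1), "os_c"),
    kroll_band = vapply(desc, `[[`, logical(1), "kroll_band"),
    area = a$area[with_formula], class = a$class[with_formula],
    size = size[with_formula],
    color = unname(.class_color(a$class[with_formula])),
    stringsAsFactors = FALSE
  )
  kk <- which(a$class == "CHO" & a$area > kendrick_area_min &
                with_formula)
  mass <- vapply(a$formula[kk], monoisotopic_mass, numeric(1),
                 USE.NAMES = FALSE)
  kendrick <- data.frame(
    id = a$id[kk],
    km = if (length(kk)) kendrick_mass(mass) else numeric(0),
    kmd = if (length(kk)) kendrick_mass_defect(mass) else numeric(0),
    area = a$area[kk],
    size = size[kk],
    stringsAsFactors = FALSE
  )
  list(mz_rt = mz_rt, van_krevelen = vk, kroll = kroll,
       kendrick = kendrick)
}
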