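#' Reference organ masses (adult male, including blood content)
#'
#' Masses in grams for the reference adult male voxel phantom, including the
#' organs' blood content where applicable: kidneys 422 g and liver 2360 g are
#' the phantom values used by the TIAC and dose calculations; the remaining
#' entries are representative reference-man values. The `remainder` mass is
#' total body minus all delineated sources, and `blood` is the 5600-g
#' reference total blood mass used to scale venous concentrations to a
#' whole-blood source fraction.
#'
#' @return A tibble with columns `organ` and `mass_g`.
#' @examples
#' reference_organ_masses()
#' @export
reference_organ_masses <- function() {
  m <- tibble::tribble(
    ~organ, ~mass_g,
    "kidneys", 422,
    "liver", 2360,
    "lungs", 1200,
    "spleen", 230,
    "salivary_glands", 85,
    "lacrimal_glands", 1.4,
    "urinary_bladder_contents", 200,
    "urinary_bladder_wall", 50,
    "blood", 5600,
    "red_bone_marrow", 1170,
    "endosteum", 1100,
    "stomach_wall", 150,
    "colon_wall", 370,
    "esophagus", 40,
    "skin", 3300,
    "testes", 35,
    "thyroid", 20,
    "brain", 1450,
    "eye_lenses", 0.4,
    "total_body", 73000
  )
  sources <- c("kidneys", "liver", "lungs", "spleen", "salivary_glands",
               "lacrimal_glands", "urinary_bladder_contents", "blood")
  rem <- m$mass_g[m$organ == "total_body"] -
    sum(m$mass_g[m$organ %in% sources])
  dplyr::bind_rows(m, tibble::tibble(organ = "remainder", mass_g = rem))
}
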