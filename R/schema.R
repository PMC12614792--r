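#' The 16-attribute perceptual schema
#'
#' Returns the fixed schema of the sixteen perceptual appearance attributes
#' that make up a visual fingerprint: for each attribute its id (1--16), name,
#' the low/high anchor terms of its rating scale, the instructive question
#' shown to raters, and a coarse cluster label grouping related attributes
#' (gloss, texture and pattern, light and colour, physical, abstract).
#'
#' @return A tibble with 16 rows and columns `id`, `name`, `anchor_low`,
#'   `anchor_high`, `question`, `cluster`.
#' @export
#' @examples
#' attribute_schema()
attribute_schema <- function() {
  tibble::tibble(
    id = 1:16,
    name = c(
      "colour vibrancy", "surface roughness", "pattern complexity",
      "striped pattern", "chequered pattern", "brightness", "shininess",
      "sparkle", "hardness", "movement effect", "pattern scale",
      "naturalness", "thickness", "multicoloured", "value", "warmth"
    ),
    anchor_low = c(
      "dull", "smooth", "plain", "no stripes", "no checks", "dark", "matt",
      "none", "soft", "none", "fine", "manmade", "flat", "single", "cheap",
      "cold"
    ),
    anchor_high = c(
      "vibrant", "rough", "complex", "pronounced stripes",
      "pronounced checks", "bright", "mirror", "sparkling", "hard",
      "extreme", "large", "natural", "thick", "many", "luxurious", "warm"
    ),
    question = c(
      "how richly coloured is the material, ranging from monochromatic or neutral-coloured materials to vibrantly coloured materials?",
      "how rough is the material, ranging from fine or smooth to coarse or grainy?",
      "how complex are the patterns on the material, ranging from simple to intricate?",
      "to what extent does the material exhibit stripy patterns?",
      "to what extent does the material exhibit chequered patterns?",
      "how bright is the material, ranging from dim or subdued to bright or luminous?",
      "how shiny is the material, ranging from dull or non-reflective to highly reflective?",
      "to what extent does the material exhibit sparkling and glittery effects?",
      "how hard is the material, ranging from soft or plush to firm or rigid?",
      "to what extent does the appearance change due to camera movement?",
      "how large are the pattern elements, ranging from fine-grained or uniform to large or blotchy patterns?",
      "how natural is the material, ranging from man-made to natural origin?",
      "how deep is the material structure, ranging from flat or thin to thick?",
      "how multicoloured is the material, ranging from a single or uniform colour to colourful or many colours?",
      "how valuable is the material, ranging from low-cost or cheap to extravagant or luxurious?",
      "how warm is the material to the touch, ranging from cool or cold to pleasant or warm?"
    ),
    cluster = c(
      "light_and_colour",    # colour vibrancy
      "texture_and_pattern", # surface roughness
      "texture_and_pattern", # pattern complexity
      "texture_and_pattern", # striped pattern
      "texture_and_pattern", # chequered pattern
      "light_and_colour",    # brightness
      "gloss",               # shininess
      "gloss",               # sparkle
      "physical",            # hardness
      "gloss",               # movement effect
      "texture_and_pattern", # pattern scale
      "abstract",            # naturalness
      "physical",            # thickness
      "light_and_colour",    # multicoloured
      "abstract",            # value
      "physical"             # warmth
    )
  )
}

#' Names of the sixteen fingerprint value columns
#'
#' Fingerprint tables store the attribute values in columns `attr01` ..
#' `attr16`, ordered by attribute id.
#'
#' @return Character vector of length 16.
#' @export
fp_cols <- function() sprintf("attr%02d", 1:16)

#' Number of fingerprint attributes
#' @return The integer 16.
#' @export
n_attributes <- function() 16L

#' Construct a fingerprint set
#'
#' A fingerprint set is a tibble with one row per material: columns
#' `material_id` (unique), `category` (optional label, may be `NA`), `scale`
#' (either `"zscore"` for aggregated z-scored ratings or `"unit"` for values
#' min--max rescaled to \[-1, 1\] over a reference corpus), and the sixteen
#' value columns `attr01` .. `attr16`.
#'
#' @param material_id Character vector of unique material ids.
#' @param values Numeric matrix (n x 16) or data frame of attribute values,
#'   columns ordered by attribute id.
#' @param scale `"zscore"` or `"unit"`.
#' @param category Optional character vector of category labels.
#' @return A validated fingerprint-set tibble.
#' @export
fingerprint_set <- function(material_id, values, scale = c("zscore", "unit"),
                            category = NA_character_) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (ncol(values) != n_attributes()) {
    rlang::abort(sprintf("`values` must have 16 columns, got %d", ncol(values)))
  }
  colnames(values) <- fp_cols()
  out <- tibble::tibble(
    material_id = as.character(material_id),
    category = rep_len(as.character(category), length(material_id)),
    scale = scale
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(values))
  validate_fingerprint_set(out)
}

#' Validate a fingerprint set
#'
#' Checks ids are unique, all sixteen value columns are present and finite,
#' all rows share one scale, and unit-scale values lie in \[-1, 1\].
#'
#' @param fps A fingerprint-set tibble.
#' @return The (invisibly unchanged) tibble, for piping.
#' @export
validate_fingerprint_set <- function(fps) {
  needed <- c("material_id", "scale", fp_cols())
  missing <- setdiff(needed, names(fps))
  if (length(missing) > 0) {
    rlang::abort(paste0("fingerprint set is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(fps) == 0) rlang::abort("fingerprint set is empty")
  if (anyDuplicated(fps$material_id)) {
    rlang::abort("fingerprint set has duplicated material_id values")
  }
  sc <- unique(fps$scale)
  if (length(sc) != 1 || !sc %in% c("zscore", "unit")) {
    rlang::abort("all fingerprints must share one scale, 'zscore' or 'unit'")
  }
  vals <- as.matrix(fps[fp_cols()])
  if (!all(is.finite(vals))) rlang::abort("fingerprint values must be finite")
  if (sc == "unit" && (min(vals) < -1 - 1e-9 || max(vals) > 1 + 1e-9)) {
    rlang::abort("unit-scale fingerprint values must lie in [-1, 1]")
  }
  if (!"category" %in% names(fps)) fps$category <- NA_character_
  fps
}

#' Extract one fingerprint's values as a numeric vector
#'
#' @param fps A fingerprint-set tibble.
#' @param material_id Id of the material to extract.
#' @return Named numeric vector of length 16.
#' @export
fingerprint_values <- function(fps, material_id) {
  row <- fps[fps$material_id == material_id, , drop = FALSE]
  if (nrow(row) != 1) {
    rlang::abort(sprintf("material '%s' not found (or duplicated)", material_id))
  }
  unlist(row[fp_cols()])
}

#' Rating-study design size
#'
#' The total number of slider responses collected by a full factorial rating
#' design: every participant rates every material on every attribute.
#'
#' @param n_attributes,n_materials,n_participants Design dimensions. Defaults
#'   are the study conditions of the reference corpus: 16 attributes, 347
#'   materials, 20 participants per attribute.
#' @return Integer count of ratings.
#' @export
#' @examples
#' rating_design_total() # 111040
rating_design_total <- function(n_attributes = 16, n_materials = 347,
                                n_participants = 20) {
  as.integer(n_attributes) * as.integer(n_materials) * as.integer(n_participants)
}

#' Boundary-anchor study design size
#'
#' Number of responses per participant when, for each of several material
#' arrangements, the lowest- and highest-valued exemplar of every attribute
#' must be picked.
#'
#' @param n_arrangements,n_attributes,n_anchors Design dimensions (defaults:
#'   3 arrangements, 16 attributes, 2 anchors per attribute).
#' @return Integer count of trials per participant.
#' @export
#' @examples
#' boundary_trials_per_participant() # 96
boundary_trials_per_participant <- function(n_arrangements = 3,
                                            n_attributes = 16,
                                            n_anchors = 2) {
  as.integer(n_arrangements) * as.integer(n_attributes) * as.integer(n_anchors)
}
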