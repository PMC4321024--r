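#' Canonical sample roles of the eleven-sample design
#'
#' The screen expects one library for each of eleven biological samples: four
#' embryo time windows (hours after oviposition), whole larvae, whole pupae,
#' adult males and females (1-5 days old), previtellogenic ovaries dissected
#' from 1-2 day old females, ovaries 24 hr post blood meal (PBM), and the
#' 24 hr PBM carcass with ovaries removed. Roles are returned in the fixed
#' order used for expression-profile displays (embryos first, then juvenile
#' stages, adults, and ovary/carcass dissections).
#'
#' @return Character vector of the 11 role names, in canonical order.
#' @export
#' @examples
#' sample_roles()
sample_roles <- function() {
  c(
    "embryo_0_1", "embryo_2_4", "embryo_4_8", "embryo_8_12",
    "larvae", "pupae", "male_1_5", "female_1_5",
    "ovary_1_2", "ovary_24pbm", "carcass_24pbm"
  )
}

#' Roles required by the differential-expression screen
#'
#' The previtellogenic ovary is contrasted against four samples that should
#' not contain female germline tissue: larvae, pupae, adult males and the
#' post-blood-meal carcass. Embryos are excluded from the contrasts because
#' maternally deposited transcripts would mask germline specificity; the
#' whole-female sample is excluded because it contains the ovary.
#'
#' @return Named list with elements `ovary` (the ovary role) and `contrasts`
#'   (the four off-target roles).
#' @export
screen_roles <- function() {
  list(
    ovary = "ovary_1_2",
    contrasts = c("larvae", "pupae", "male_1_5", "carcass_24pbm")
  )
}

embryo_roles <- function() {
  c("embryo_0_1", "embryo_2_4", "embryo_4_8", "embryo_8_12")
}

#' Validate a sample sheet
#'
#' A sample sheet maps each count-matrix column to one of the canonical
#' roles. Roles must be drawn from [sample_roles()] and each role may appear
#' at most once (the design has one library per sample).
#'
#' @param samples Data frame with columns `sample_id` and `role`.
#' @param require_screen_roles If `TRUE`, additionally require the ovary and
#'   the four contrast roles needed to run the screen.
#' @return The sample sheet as a tibble, invisibly validated.
#' @export
validate_sample_sheet <- function(samples, require_screen_roles = FALSE) {
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "role") %in% names(samples))) {
    abort("sample sheet must have columns 'sample_id' and 'role'",
          class = "ovascreen_format_error")
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$role <- as.character(samples$role)
  bad <- setdiff(samples$role, sample_roles())
  if (length(bad) > 0) {
    abort(paste0("unknown sample role(s): ", paste(bad, collapse = ", ")),
          class = "ovascreen_format_error")
  }
  if (anyDuplicated(samples$role)) {
    abort("each role may appear at most once in a sample sheet",
          class = "ovascreen_format_error")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample_id in sample sheet",
          class = "ovascreen_format_error")
  }
  if (require_screen_roles) {
    need <- c(screen_roles()$ovary, screen_roles()$contrasts)
    missing <- setdiff(need, samples$role)
    if (length(missing) > 0) {
      abort(paste0("screen requires roles missing from sample sheet: ",
                   paste(missing, collapse = ", ")),
            class = "ovascreen_config_error")
    }
  }
  samples
}

# sample_id of the column carrying `role`, or error
role_sample <- function(samples, role) {
  hit <- samples$sample_id[samples$role == role]
  if (length(hit) != 1) {
    abort(paste0("role '", role, "' not present in sample sheet"),
          class = "ovascreen_config_error")
  }
  hit
}
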