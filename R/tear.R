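# Radial tears of the medial meniscus and total meniscectomy, created by
# partially removing elements from the intact mesh (the intact and torn
# meshes share topology, so matched-location comparisons are index-based).

#' Specify a medial meniscus radial tear (or total meniscectomy)
#'
#' A radial tear runs from the inner rim outward across `width_fraction` of
#' the local meniscus width, within a one-element-column circumferential slot
#' at `position_frac` of the chosen sector (0 = sector start nearer the
#' anterior horn end, 1 = sector end; default mid-sector).
#'
#' @param location one of `"anterior_horn"`, `"midbody"`, `"posterior_horn"`.
#' @param width_fraction fraction of the meniscus width torn, in (0, 1); the
#'   study grades are 0.33, 0.50 and 0.83.
#' @param position_frac tear position within the sector, in [0, 1].
#' @param total_meniscectomy if TRUE the whole medial meniscus is resected
#'   (the other fields are ignored).
#' @return a validated `tear_spec`.
#' @export
tear_spec <- function(location = c("midbody", "anterior_horn", "posterior_horn"),
                      width_fraction = 0.33, position_frac = 0.5,
                      total_meniscectomy = FALSE) {
  if (total_meniscectomy) {
    out <- list(total_meniscectomy = TRUE, location = NA_character_,
                width_fraction = NA_real_, position_frac = NA_real_)
    class(out) <- "tear_spec"
    return(out)
  }
  location <- match.arg(location)
  if (!is.numeric(width_fraction) || width_fraction <= 0 || width_fraction >= 1) {
    stop("field 'width_fraction' must lie in (0, 1) unless total_meniscectomy")
  }
  if (position_frac < 0 || position_frac > 1) {
    stop("field 'position_frac' must lie in [0, 1]")
  }
  out <- list(total_meniscectomy = FALSE, location = location,
              width_fraction = width_fraction, position_frac = position_frac)
  class(out) <- "tear_spec"
  out
}

#' Apply a radial tear or meniscectomy to a knee model
#'
#' Element removal: the tear occupies exactly one element column in the
#' circumferential direction; within it, the innermost
#' `round(width_fraction * n_rad)` radial element rings are removed through
#' the full thickness. The remaining radially-adjacent elements of the same
#' column are tagged as the tear tip. Total meniscectomy removes the medial
#' meniscus body, its contact pairs, horn springs and the transverse
#' ligament coupling.
#'
#' @param model an intact `knee_model` (medial meniscus present).
#' @param tear a `tear_spec`.
#' @return a new `knee_model` (variant label set accordingly).
#' @export
apply_radial_tear <- function(model, tear) {
  stopifnot(inherits(model, "knee_model"), inherits(tear, "tear_spec"))
  men <- model$bodies$medial_meniscus
  if (is.null(men)) stop("model has no medial meniscus to tear")

  if (tear$total_meniscectomy) {
    model$bodies$medial_meniscus <- NULL
    model$frames$medial_meniscus <- NULL
    model$contact_pairs <- setdiff(model$contact_pairs,
                                   c("femoral_cartilage-medial_meniscus",
                                     "medial_meniscus-medial_tibial_cartilage"))
    model$horn_springs <- model$horn_springs[
      !grepl("^medial_meniscus", names(model$horn_springs))]
    model$transverse_springs <- NULL
    model$tear_tip$medial_meniscus <- integer(0)
    model$variant <- "meniscectomy"
    return(model)
  }

  spec <- model$spec
  nc <- spec$n_circ; nr <- spec$n_rad
  sec_in_col <- men$sector[men$ijk[, 2] == 1 & men$ijk[, 3] == 1]
  cols <- which(sec_in_col == tear$location)
  if (length(cols) == 0) stop("tear sector outside the annulus")
  col <- cols[1 + floor(tear$position_frac * (length(cols) - 1e-9))]
  n_rm <- round(tear$width_fraction * nr)
  if (n_rm == 0) {
    model$variant <- sprintf("%s_%02d", tear$location,
                             round(100 * tear$width_fraction))
    model$tear_tip$medial_meniscus <-
      which(men$ijk[, 1] == col & men$ijk[, 2] == 1)
    return(model)   # removal band empty: geometry unchanged
  }
  if (n_rm >= nr) stop("width_fraction removes the full width; use total_meniscectomy")

  rm_el <- which(men$ijk[, 1] == col & men$ijk[, 2] <= n_rm)
  tip_el_old <- which(men$ijk[, 1] == col & men$ijk[, 2] == n_rm + 1)
  keep <- setdiff(seq_len(nrow(men$elems)), rm_el)

  men$elems <- men$elems[keep, , drop = FALSE]
  men$ijk <- men$ijk[keep, , drop = FALSE]
  men$sector <- men$sector[keep]
  men$angle <- men$angle[keep]
  model$frames$medial_meniscus <- model$frames$medial_meniscus[keep]
  model$bodies$medial_meniscus <- men
  model$tear_tip$medial_meniscus <- match(tip_el_old, keep)
  model$variant <- sprintf("%s_%02d", tear$location,
                           round(100 * tear$width_fraction))

  if (mesh_components(men$elems) != 1) {
    stop("tear disconnects the medial meniscus")
  }
  model
}

#' Matched tear-tip element set on an intact model
#'
#' Because torn meshes are made by deletion, the intact model's elements at
#' the same spatial location as a tear tip are found by the same
#' (column, ring) indices.
#'
#' @param model an intact `knee_model`.
#' @param tear the `tear_spec` whose tip location is wanted.
#' @return integer element ids into the intact medial meniscus.
#' @export
matched_tip_elements <- function(model, tear) {
  stopifnot(!tear$total_meniscectomy)
  men <- model$bodies$medial_meniscus
  spec <- model$spec
  nr <- spec$n_rad
  sec_in_col <- men$sector[men$ijk[, 2] == 1 & men$ijk[, 3] == 1]
  cols <- which(sec_in_col == tear$location)
  col <- cols[1 + floor(tear$position_frac * (length(cols) - 1e-9))]
  n_rm <- max(round(tear$width_fraction * nr), 0)
  ring <- min(n_rm + 1, nr)
  which(men$ijk[, 1] == col & men$ijk[, 2] == ring)
}
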