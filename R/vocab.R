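# Canonical vocabularies for the coronary angiography pipeline.

#' Canonical coronary segment scheme
#'
#' The 11 coronary artery segments used throughout the pipeline, after the
#' report-merging rules (ostial merged into proximal; all left-main
#' subdivisions merged into a single left-main class). Side branches
#' (diagonals, marginals, septals, ramus) and grafts are excluded.
#'
#' @return character vector of 11 canonical segment labels.
#' @export
coronary_segments <- function() {
  c("lm",
    "lad_prox", "lad_mid", "lad_dist",
    "lcx_prox", "lcx_mid", "lcx_dist",
    "rca_prox", "rca_mid", "rca_dist",
    "pda")
}

#' Segments belonging to each coronary tree
#' @param side `"LCA"` or `"RCA"`.
#' @return character vector of segment labels on that tree.
#' @export
tree_segments <- function(side) {
  switch(toupper(side),
    LCA = c("lm", "lad_prox", "lad_mid", "lad_dist",
            "lcx_prox", "lcx_mid", "lcx_dist"),
    RCA = c("rca_prox", "rca_mid", "rca_dist", "pda"),
    stop("unknown side: ", side)
  )
}

#' Anatomic structure classes
#'
#' The 11 classes describing the primary anatomic structure of an
#' angiogram video. Only the two coronary classes flow on to lesion
#' localization.
#'
#' @return character vector of 11 class labels.
#' @export
anatomy_classes <- function() {
  c("lca", "rca", "bypass_graft", "pci", "catheter", "pigtail_catheter",
    "ventriculography", "radial_artery", "femoral_artery", "aortography",
    "other")
}

#' Object-detection vocabulary
#'
#' Classes localized by the lesion detector: the 11 coronary segments plus
#' stenosis and device classes. Device/lesion classes are never touched by
#' the projection-exclusion heuristic, which only removes artery segments.
#'
#' @return character vector of detector class labels.
#' @export
detector_classes <- function() {
  c(coronary_segments(), "stenosis", "guidewire", "catheter", "sternotomy")
}

# Classes the projection heuristic may remove (artery segments only).
segment_classes <- function() coronary_segments()
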