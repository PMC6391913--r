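#' Dissolve marker clusters below a minimum size
#'
#' Clusters represented by fewer than `min_n` marker proteins *present in
#' the experiment* are dissolved: their proteins are relabelled as
#' unknown. Sub-cellular niches defined by a handful of markers give
#' noisy within-cluster distance estimates, so a minimum of 7 markers per
#' cluster is required by default before an experiment is scored.
#' The threshold is inclusive: a cluster of exactly `min_n` markers
#' survives. Idempotent.
#'
#' @param mk a `MarkerAnnotation`.
#' @param exp a `ProfileExperiment`; only markers whose protein is present
#'   count towards the threshold. `NULL` counts all assignments.
#' @param min_n minimum markers per cluster (>= 2, default 7).
#' @return the filtered `MarkerAnnotation`; dissolved cluster names are
#'   attached as attribute `"dissolved"` and reported via `message()`.
#' @export
filter_min_markers <- function(mk, exp = NULL, min_n = 7L) {
  stopifnot(inherits(mk, "MarkerAnnotation"))
  if (min_n < 2L) stop("'min_n' must be at least 2")
  lab <- unclass(mk)
  present <- if (is.null(exp)) lab
             else lab[names(lab) %in% protein_ids(exp)]
  cnt <- table(present[present != unknown_label(mk)])
  drop <- names(cnt)[cnt < min_n]
  ## also dissolve clusters with zero presence in the experiment
  drop <- union(drop, setdiff(cluster_labels(mk), names(cnt)))
  if (length(drop)) {
    message("dissolving ", length(drop), " cluster(s) with < ", min_n,
            " markers: ", paste(sort(drop), collapse = ", "))
    lab[lab %in% drop] <- unknown_label(mk)
  }
  out <- marker_annotation(lab, unknown_label = unknown_label(mk))
  if (length(cluster_labels(out)) < 2L)
    stop("fewer than 2 clusters survive the minimum-marker filter")
  attr(out, "dissolved") <- sort(drop)
  out
}

#' Transfer a marker annotation onto another experiment
#'
#' Annotates `target_exp` with `source`'s labels by exact protein
#' identifier match: every target protein found in `source` (with a
#' non-unknown label) receives the source label, replacing any native
#' annotation; all other proteins become unknown. The minimum-size filter
#' is then re-applied, because intersecting identifier sets shrinks
#' clusters. An optional `normalise_id` function (e.g. stripping
#' accession versions) is applied to both sides before matching; exact
#' equality is the default because curated marker lists within one
#' species share an identifier namespace.
#'
#' @param source a `MarkerAnnotation` (the donor marker set).
#' @param target_exp a `ProfileExperiment` to annotate.
#' @param min_n minimum markers per cluster after transfer (default 7).
#' @param normalise_id optional function applied to identifiers on both
#'   sides before matching.
#' @return the transferred, filtered `MarkerAnnotation` on
#'   `target_exp`'s proteins.
#' @export
transfer_markers <- function(source, target_exp, min_n = 7L,
                             normalise_id = identity) {
  stopifnot(inherits(source, "MarkerAnnotation"),
            inherits(target_exp, "ProfileExperiment"))
  src <- unclass(source)
  src <- src[src != unknown_label(source)]
  src_ids <- normalise_id(names(src))
  tgt_ids <- protein_ids(target_exp)
  hit <- match(normalise_id(tgt_ids), src_ids)
  if (!any(!is.na(hit)))
    stop("no shared protein identifiers between source markers and target")
  lab <- rep(unknown_label(source), length(tgt_ids))
  lab[!is.na(hit)] <- unname(src[hit[!is.na(hit)]])
  names(lab) <- tgt_ids
  mk <- marker_annotation(lab, unknown_label = unknown_label(source))
  filter_min_markers(mk, target_exp, min_n = min_n)
}
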