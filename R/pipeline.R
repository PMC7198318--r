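#' Generate summaries, metadata and a ledger for a whole plan
#'
#' Runs the back half of the pipeline: for every view root in the plan,
#' collects the view, decides against the previous ledger whether a new
#' summary is needed, renders the summary document pair and its metadata
#' record, and writes an updated ledger.  Views with an unchanged snapshot
#' are skipped (their existing ledger entry is carried forward).
#'
#' @param h A [hierarchy()] with contributors and references merged.
#' @param plan A [recommend_views()] plan.
#' @param db_version Database version label for the titles.
#' @param publisher Publisher string.
#' @param out_dir Output directory; summaries go to `out_dir/summaries`,
#'   metadata to `out_dir/metadata`, the ledger to `out_dir/ledger.json`.
#' @param prev_ledger Named list of [ledger_entry()] objects from the
#'   previous run (e.g. [read_ledger()]), or `NULL` for a first run.
#' @param force Regenerate every view regardless of detected changes.
#' @param include_objects Passed to [collect_view()].
#' @return Invisibly, a list with `generated` (view ids regenerated),
#'   `skipped` (view ids carried forward) and `ledger` (the new ledger).
#' @export
generate_summaries <- function(h, plan, db_version,
                               publisher = "Synthetic Curators Consortium",
                               out_dir = ".", prev_ledger = NULL,
                               force = FALSE, include_objects = TRUE) {
  stopifnot(inherits(plan, "summary_plan"))
  sum_dir <- file.path(out_dir, "summaries")
  meta_dir <- file.path(out_dir, "metadata")
  dir.create(sum_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(meta_dir, showWarnings = FALSE, recursive = TRUE)

  generated <- character(0)
  skipped <- character(0)
  ledger <- list()
  for (root in plan$roots$node_id) {
    view <- collect_view(h, root, include_objects = include_objects)
    prev <- prev_ledger[[root]]
    version <- "1"
    if (!is.null(prev)) {
      check <- needs_new_summary(prev, view, force = force)
      if (!check$decision) {
        ledger[[root]] <- prev
        skipped <- c(skipped, root)
        next
      }
      version <- next_version(prev$summary_version)
    }
    s <- render_summary(view, db_version = db_version, publisher = publisher,
                        summary_version = version)
    write_summary(s, sum_dir)
    xml2::write_xml(render_metadata(s),
                    file.path(meta_dir, paste0(root, ".xml")))
    ledger[[root]] <- summary_ledger_entry(s)
    generated <- c(generated, root)
  }
  write_ledger(ledger, file.path(out_dir, "ledger.json"))
  invisible(list(generated = generated, skipped = skipped, ledger = ledger))
}
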