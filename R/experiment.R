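#' Reconstruct the test portion of one preprocessed record
#'
#' Feeds the record's test-split PPG segments through the model, stitches
#' the outputs, and returns them next to the gap-free reference ECG of the
#' same span.
#'
#' @param model A trained `wnet_model`.
#' @param segments A [preprocess_record()] result.
#' @param split A [split_segments()] result for this record.
#' @return List with `reference` and `reconstructed` numeric vectors
#'   (length = test segments x segment length) and `record_id`.
#' @export
reconstruct_record <- function(model, segments, split) {
  stopifnot(inherits(segments, "segment_set"))
  recon <- predict(model, segments$ppg[, split$test, drop = FALSE])
  list(reference = stitch(segments$ecg[, split$test, drop = FALSE]),
       reconstructed = stitch(recon),
       record_id = segments$record_id)
}

#' Plan a reconstruction experiment
#'
#' An experiment evaluates each model variant for each missing-data length:
#' gaps of 1-4 s are labeled experiments I-IV.
#'
#' @param gaps Gap lengths in seconds (default `c(1, 2, 3, 4)`).
#' @param variants Model variants to train.
#' @param config A [default_config()] list (seed, training budget, split).
#' @param n_records Number of synthetic records to simulate when no
#'   `records` are supplied.
#' @param records Optional list of [new_record()] objects to use instead of
#'   simulation.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A list of class `experiment_plan`.
#' @export
experiment_plan <- function(gaps = c(1, 2, 3, 4), variants = "wnet",
                            config = default_config(), n_records = 10L,
                            records = NULL, out_dir = NULL) {
  stopifnot(all(variants %in% c("wnet", "wnet_bilstm")))
  structure(list(gaps = gaps, variants = variants, config = config,
                 n_records = as.integer(n_records), records = records,
                 out_dir = out_dir),
            class = "experiment_plan")
}

roman_label <- function(gap_seconds) {
  lbl <- c("1" = "I", "2" = "II", "3" = "III", "4" = "IV")
  out <- lbl[as.character(gap_seconds)]
  ifelse(is.na(out), paste0("gap", gap_seconds, "s"), out)
}

#' Run a full reconstruction experiment
#'
#' The complete pipeline, per (variant, gap) cell: simulate (or take)
#' paired records, preprocess each (filter, Alignment I, normalize,
#' segment), inject one seeded ECG gap per record into its training
#' portion, train one group model jointly across records, reconstruct each
#' record's test portion, evaluate before/after Alignment II, and
#' summarize.  With `out_dir` set, per-record metric CSVs, summary CSVs,
#' and a run manifest (config, seeds) are written.
#'
#' @param plan An [experiment_plan()].
#' @param quiet Suppress per-stage progress messages.
#' @return List with `summary` (one data frame over all cells), `reports`
#'   (nested per cell/record), and `manifest`.
#' @export
run_experiment <- function(plan, quiet = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  cfg <- plan$config
  say <- function(...) if (!quiet) message(sprintf(...))

  records <- plan$records
  if (is.null(records)) {
    say("[simulate] %d records", plan$n_records)
    records <- simulate_records(plan$n_records,
                                seed = derive_seed(cfg$seed, "simulate"))
  }
  say("[preprocess] %d records", length(records))
  prepped <- lapply(records, function(r) {
    tryCatch(preprocess_record(r, cfg),
             error = function(e) stop("stage preprocess, record ", r$record_id,
                                      ": ", conditionMessage(e)))
  })
  split <- split_segments(ncol(prepped[[1]]$ecg), cfg)

  all_summaries <- list()
  all_reports <- list()
  for (variant in plan$variants) {
    for (gap in plan$gaps) {
      label <- roman_label(gap)
      cell <- sprintf("%s_gap%gs", variant, gap)
      say("[train] %s, experiment %s (gap %g s)", variant, label, gap)
      gapped <- lapply(prepped, function(sg) {
        inject_gap(sg, gap,
                   seed = derive_seed(cfg$seed, paste0("gap_", gap, "_", sg$record_id)),
                   split = split, cfg = cfg)
      })
      train_ppg <- do.call(cbind, lapply(gapped, function(s) s$ppg[, split$train]))
      train_ecg <- do.call(cbind, lapply(gapped, function(s) s$ecg[, split$train]))
      train_mask <- do.call(cbind, lapply(gapped, function(s) s$mask[, split$train]))
      val_ppg <- do.call(cbind, lapply(gapped, function(s) s$ppg[, split$val]))
      val_ecg <- do.call(cbind, lapply(gapped, function(s) s$ecg[, split$val]))

      spec <- model_spec(variant, in_len = nrow(train_ppg),
                         seed = derive_seed(cfg$seed, paste0("init_", cell)),
                         allow_nonstandard = nrow(train_ppg) != 375L)
      model <- build_model(spec)
      model <- train_model(model, train_ppg, train_ecg, val_ppg, val_ecg,
                           cfg = cfg, train_mask = train_mask,
                           seed = derive_seed(cfg$seed, paste0("train_", cell)))
      say("[evaluate] %s: best val loss %.5f (epoch %d)", cell,
          model$history$best_val_loss, model$history$best_epoch)
      reports <- lapply(gapped, function(sg) {
        rec <- reconstruct_record(model, sg, split)
        evaluate_record(rec$reference, rec$reconstructed, cfg,
                        record_id = rec$record_id)
      })
      all_reports[[cell]] <- reports
      summ <- summarize_reports(reports, experiment = label)
      summ$variant <- variant
      summ$gap_seconds <- gap
      all_summaries[[cell]] <- summ

      if (!is.null(plan$out_dir)) {
        dir.create(plan$out_dir, recursive = TRUE, showWarnings = FALSE)
        per_rec <- do.call(rbind, lapply(reports, function(rp) {
          do.call(rbind, lapply(rp, function(side) {
            data.frame(record_id = side$record_id,
                       aligned = side$aligned, lag_samples = side$lag_samples,
                       r = side$r, rmse = side$rmse, prd = side$prd,
                       fd = side$fd, stringsAsFactors = FALSE)
          }))
        }))
        utils::write.csv(per_rec,
                         file.path(plan$out_dir, paste0("metrics_", cell, ".csv")),
                         row.names = FALSE)
        save_model(model, file.path(plan$out_dir, paste0("model_", cell, ".rds")))
      }
    }
  }
  summary_df <- do.call(rbind, all_summaries)
  rownames(summary_df) <- NULL
  manifest <- list(
    config = unclass(cfg),
    n_records = length(records),
    record_ids = vapply(records, `[[`, character(1), "record_id"),
    gaps = plan$gaps, variants = plan$variants,
    package_version = as.character(utils::packageVersion("ppg2ecg")))
  if (!is.null(plan$out_dir)) {
    utils::write.csv(summary_df, file.path(plan$out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(plan$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summary_df, reports = all_reports, manifest = manifest)
}
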