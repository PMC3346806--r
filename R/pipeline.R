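#' Default run configuration
#'
#' Every threshold of the screening cascade with its standard default:
#' keyword list; cysteine/length minima (2 / 55); homology-annotation triple
#' (alignment length > 50, e-value <= 5e-4, similarity > 30 percent); fl/pl
#' band 0.6-1.3 and maximal gap 10; SCOP coverage >= 70 percent, top 20
#' domains, chemokine rank <= 2; disulfide criteria (10 A, 9 A, 1 A,
#' separation >= 3); Thx weights and top-n (70).
#'
#' @param ... named overrides, e.g. `default_config(seed = 7, top_n = 10)`.
#' @return a named list of class `chemoscan_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    input = list(fasta = NULL, homology_hits = NULL,
                 sp_pred_a = NULL, sp_pred_b = NULL,
                 tm_pred_a = NULL, tm_pred_b = NULL,
                 blacklist = NULL),
    keywords = c("unknown", "orf", "hypothetical", "uncharacterized", "putative"),
    min_cys = 2, min_len = 55,
    annotation = list(min_len = 50, max_eval = 5e-4, min_sim = 30),
    gap_open = 4.0, gap_extend = 0.4, n_shuffles = 100,
    w_pair = 1, w_surf = 1, w_seq = 1, thx_scale = 100,
    ratio_lo = 0.6, ratio_hi = 1.3, max_gap = 10, edge_slack = 1,
    min_cov = 70, top_domains = 20, max_ck_rank = 2,
    disulfide = list(d_ca_max = 10, d_cb_max = 9, d_diff_max = 1,
                     min_sep = 3, mode = "any", max_cys = 20),
    min_bonds = 1, top_n = 70,
    thx_cutoff = NULL, calibration_query = NULL,
    seed = 1L, output_dir = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) && nm != "input") {
      for (k in names(dots[[nm]])) cfg[[nm]][k] <- list(dots[[nm]][[k]])
    } else if (nm == "input" && is.list(dots[[nm]])) {
      for (k in names(dots[[nm]])) cfg[[nm]][k] <- list(dots[[nm]][[k]])
    } else {
      cfg[nm] <- list(dots[[nm]])  # preserves explicit NULLs
    }
  }
  class(cfg) <- "chemoscan_config"
  cfg
}

#' Read / write a run configuration as YAML (lossless round-trip)
#'
#' @param path YAML file.
#' @return a `chemoscan_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

#' @rdname read_config
#' @param config a `chemoscan_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' @param config a `chemoscan_config`.
#' @param need_inputs require input file paths to exist (default TRUE).
#' @return TRUE invisibly; otherwise an error listing the offending fields.
#' @export
validate_config <- function(config, need_inputs = TRUE) {
  problems <- character()
  num_fields <- c("min_cys", "min_len", "gap_open", "gap_extend", "n_shuffles",
                  "ratio_lo", "ratio_hi", "max_gap", "min_cov", "top_domains",
                  "max_ck_rank", "min_bonds", "top_n", "seed")
  for (f in num_fields) {
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1 || is.na(config[[f]]))
      problems <- c(problems, f)
  }
  if (need_inputs) {
    for (f in c("fasta")) {
      p <- config$input[[f]]
      if (is.null(p) || !file.exists(p)) problems <- c(problems, paste0("input$", f))
    }
  }
  if (is.null(config$thx_cutoff) && is.null(config$calibration_query))
    problems <- c(problems, "thx_cutoff/calibration_query (one required)")
  if (length(problems) > 0)
    stop_scan("invalid configuration field(s): %s", paste(problems, collapse = ", "))
  invisible(TRUE)
}

#' Write sequence records to FASTA
#'
#' @param records list of `sequence_record`.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    hdr <- if (nzchar(r$accession)) sprintf(">tr|%s|%s %s", r$accession, r$id, r$description)
           else sprintf(">%s %s", r$id, r$description)
    c(trimws(hdr), r$residues)
  }))
  writeLines(lines %||% character(), path)
  invisible(path)
}

stage_decision <- function(query_id, stage, verdict, reason = "", value = NA_real_) {
  tibble(query_id = query_id, stage = stage, verdict = verdict,
         reason = reason, value = value)
}

#' Run the full screening cascade
#'
#' Stage 1: keyword selection and cysteine check. Stage 2: homology
#' annotation filter, consensus signal-peptide/transmembrane trimming,
#' cysteine/length re-check. Stage 3: chemokine 3D-profile screen (threading
#' + scaffold disulfide mapping) and top-n selection. Stage 4: fold-space
#' control screen (chemokine fold must rank 1-2 among high-confidence SCOP
#' domains). An optional annotation blacklist removes queries whose external
#' annotations contradict a chemokine fold. Deterministic for a fixed
#' configuration and seed.
#'
#' @param config a `chemoscan_config` (see [default_config()]). In addition
#'   to file-path inputs, `chemokine_library`, `foldspace_library` and
#'   `potentials` must be supplied (as objects in the config, built with
#'   [build_chemokine_library()] etc.).
#' @return object of class `screen_report`: per-stage counts, per-query
#'   decisions, survivors, config hash and seed.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  if (is.null(config$chemokine_library) || is.null(config$foldspace_library) ||
      is.null(config$potentials))
    stop_scan("config must carry chemokine_library, foldspace_library and potentials")
  seed <- as.integer(config$seed)
  cfg_hash <- rlang::hash(unclass(config)[setdiff(names(config),
                                                  c("chemokine_library",
                                                    "foldspace_library",
                                                    "potentials"))])
  decisions <- list()
  counts <- list()

  ## Stage 1: extraction -------------------------------------------------
  records <- read_fasta(config$input$fasta)
  n0 <- length(records)
  records <- keyword_filter(records, config$keywords)
  stage1 <- list()
  for (r in records) {
    ok <- cys_count(r$residues) >= config$min_cys
    decisions[[length(decisions) + 1]] <-
      stage_decision(r$id, "1_extraction", if (ok) "keep" else "drop",
                     if (ok) "" else "cysteines", cys_count(r$residues))
    if (ok) stage1[[length(stage1) + 1]] <- r
  }
  counts$`1_extraction` <- c(n_in = n0, n_out = length(stage1))

  ## Stage 2: pre-filtering ----------------------------------------------
  hits_all <- if (!is.null(config$input$homology_hits))
    parse_homology_hits(config$input$homology_hits) else NULL
  sp_a <- if (!is.null(config$input$sp_pred_a)) read_sp_predictions(config$input$sp_pred_a) else NULL
  sp_b <- if (!is.null(config$input$sp_pred_b)) read_sp_predictions(config$input$sp_pred_b) else NULL
  tm_a <- if (!is.null(config$input$tm_pred_a)) read_tm_predictions(config$input$tm_pred_a) else NULL
  tm_b <- if (!is.null(config$input$tm_pred_b)) read_tm_predictions(config$input$tm_pred_b) else NULL

  stage2 <- list()
  for (r in stage1) {
    if (!is.null(hits_all)) {
      af <- annotation_filter(r, hits_all[hits_all$query_id == r$id, ],
                              config$annotation$min_len,
                              config$annotation$max_eval,
                              config$annotation$min_sim)
      if (!af$keep) {
        decisions[[length(decisions) + 1]] <-
          stage_decision(r$id, "2_prefilter", "drop", "annotated_by_homology")
        next
      }
    }
    regions <- NULL
    pick <- function(tbl, id) {
      if (is.null(tbl)) return(NULL)
      row <- tbl[tbl$id == id, ]
      if (nrow(row) == 0) NULL else row
    }
    pa <- pick(sp_a, r$id); pb <- pick(sp_b, r$id)
    if (!is.null(pa) && !is.null(pb)) {
      sp <- consensus_signal_peptide(
        list(has_sp = pa$has_sp, cleavage_pos = pa$cleavage_pos),
        list(has_sp = pb$has_sp, cleavage_pos = pb$cleavage_pos))
      if (!is.null(sp) && sp$end <= nchar(r$residues)) regions <- bind_rows(regions, sp)
    }
    ta <- pick(tm_a, r$id); tb <- pick(tm_b, r$id)
    if (!is.null(ta) && !is.null(tb)) {
      tm <- consensus_transmembrane(ta$intervals[[1]], tb$intervals[[1]])
      tm <- tm[tm$end <= nchar(r$residues), , drop = FALSE]
      regions <- bind_rows(regions, tm)
    }
    if (!is.null(regions) && nrow(regions) > 0) r <- apply_region_removal(r, regions)
    clf <- cys_length_filter(r, config$min_cys, config$min_len)
    decisions[[length(decisions) + 1]] <-
      stage_decision(r$id, "2_prefilter", if (clf$pass) "keep" else "drop",
                     clf$reason, nchar(r$residues))
    if (clf$pass) stage2[[length(stage2) + 1]] <- r
  }
  counts$`2_prefilter` <- c(n_in = length(stage1), n_out = length(stage2))

  ## Stage 3: chemokine 3D profiling --------------------------------------
  thx_cutoff <- config$thx_cutoff
  if (is.null(thx_cutoff)) {
    thx_cutoff <- calibrate_thx_cutoff(config$calibration_query,
                                       config$chemokine_library,
                                       config$potentials, seed = seed,
                                       n_shuffles = config$n_shuffles,
                                       gap_open = config$gap_open,
                                       gap_extend = config$gap_extend,
                                       w_pair = config$w_pair,
                                       w_surf = config$w_surf,
                                       w_seq = config$w_seq,
                                       scale = config$thx_scale)
  }
  stage3 <- list()
  scores <- list()
  for (r in stage2) {
    scr <- chemokine_profile_screen(
      r, config$chemokine_library, config$potentials, thx_cutoff,
      min_bonds = config$min_bonds, seed = seed,
      n_shuffles = config$n_shuffles, gap_open = config$gap_open,
      gap_extend = config$gap_extend, w_pair = config$w_pair,
      w_surf = config$w_surf, w_seq = config$w_seq, scale = config$thx_scale)
    decisions[[length(decisions) + 1]] <-
      stage_decision(r$id, "3_chemokine_profile",
                     if (scr$pass) "keep" else "drop", scr$reason,
                     scr$best_thx)
    if (scr$pass) {
      stage3[[length(stage3) + 1]] <- r
      scores[[length(scores) + 1]] <- tibble(query_id = r$id,
                                             best_thx = scr$best_thx)
    }
  }
  counts$`3_chemokine_profile` <- c(n_in = length(stage2), n_out = length(stage3))

  ## top-n selection ------------------------------------------------------
  if (length(stage3) > 0) {
    sc <- bind_rows(scores)
    top <- take_top(sc, n = config$top_n)
    keep_ids <- top$query_id
    for (r in stage3) {
      if (!r$id %in% keep_ids) {
        decisions[[length(decisions) + 1]] <-
          stage_decision(r$id, "3b_top_n", "drop", "below_top_n")
      }
    }
    stage3b <- Filter(function(r) r$id %in% keep_ids, stage3)
  } else {
    stage3b <- list()
  }
  counts$`3b_top_n` <- c(n_in = length(stage3), n_out = length(stage3b))

  ## Stage 4: fold-space control ------------------------------------------
  stage4 <- list()
  for (r in stage3b) {
    fs <- foldspace_screen(r, config$foldspace_library, config$potentials,
                           seed = seed, min_cov = config$min_cov,
                           top_domains = config$top_domains,
                           max_ck_rank = config$max_ck_rank,
                           n_shuffles = config$n_shuffles,
                           gap_open = config$gap_open,
                           gap_extend = config$gap_extend,
                           w_pair = config$w_pair, w_surf = config$w_surf,
                           w_seq = config$w_seq, scale = config$thx_scale)
    decisions[[length(decisions) + 1]] <-
      stage_decision(r$id, "4_fold_space", if (fs$pass) "keep" else "drop",
                     fs$reason, as.numeric(fs$ck_rank))
    if (fs$pass) stage4[[length(stage4) + 1]] <- r
  }
  counts$`4_fold_space` <- c(n_in = length(stage3b), n_out = length(stage4))

  ## optional annotation blacklist ----------------------------------------
  final <- stage4
  if (!is.null(config$input$blacklist) && file.exists(config$input$blacklist)) {
    bl <- readLines(config$input$blacklist)
    bl <- trimws(bl[nzchar(trimws(bl)) & !startsWith(bl, "#")])
    bl_ids <- vapply(strsplit(bl, "\t"), `[[`, character(1), 1)
    final <- list()
    for (r in stage4) {
      if (r$id %in% bl_ids) {
        decisions[[length(decisions) + 1]] <-
          stage_decision(r$id, "5_blacklist", "drop", "contradicting_annotation")
      } else final[[length(final) + 1]] <- r
    }
    counts$`5_blacklist` <- c(n_in = length(stage4), n_out = length(final))
  }

  stage_counts <- bind_rows(lapply(names(counts), function(s)
    tibble(stage = s, n_in = counts[[s]][["n_in"]], n_out = counts[[s]][["n_out"]])))
  report <- structure(list(
    stage_counts = stage_counts,
    decisions = bind_rows(decisions),
    survivors = final,
    thx_cutoff = thx_cutoff,
    config_hash = cfg_hash,
    seed = seed
  ), class = "screen_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_screen_report(report, config$output_dir)
    write_fasta(final, file.path(config$output_dir, "survivors.fasta"))
  }
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  for (k in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %-20s %4d -> %4d\n", x$stage_counts$stage[k],
                x$stage_counts$n_in[k], x$stage_counts$n_out[k]))
  }
  cat(sprintf("  Thx cutoff %.3f, seed %d, config %s\n",
              x$thx_cutoff, x$seed, x$config_hash))
  invisible(x)
}

#' Write a screen report as JSON and TSV
#'
#' @param report a `screen_report`.
#' @param dir output directory.
#' @export
write_screen_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    provenance = list(config_hash = report$config_hash, seed = report$seed,
                      thx_cutoff = report$thx_cutoff),
    stage_counts = report$stage_counts,
    decisions = report$decisions,
    survivors = vapply(report$survivors, function(r) r$id, character(1))
  ), file.path(dir, "screen_report.json"), digits = NA, auto_unbox = TRUE)
  tsv <- file.path(dir, "decisions.tsv")
  con <- file(tsv, "w")
  writeLines(sprintf("# chemoscan screen report; config=%s seed=%d",
                     report$config_hash, report$seed), con)
  close(con)
  suppressWarnings(write.table(report$decisions, tsv, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(dir)
}
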