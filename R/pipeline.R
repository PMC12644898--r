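#' Default pipeline configuration
#'
#' Returns the nested configuration list understood by [run_pipeline()],
#' pre-filled with the study's analysis settings (scan threshold 1e-4,
#' q <= 0.5, 500-bp CREs, 60/20/20 split, the boosted-tree
#' hyperparameters) and a two-class synthetic recovery design for the
#' `simulate` stage. Override any entry, or load a YAML file with
#' [read_pipeline_config()].
#'
#' @param seed Master seed recorded in every stage manifest.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(classes = c("classA", "classB"),
                    n_per_class = 500L, cre_width = 500L,
                    n_discriminative = 5L, n_decoy = 20L,
                    width_range = c(8L, 12L), concentration = 50,
                    rate_target = 0.8, rate_background = 0.05,
                    decoy_rate = 0.3, gc = 0.41),
    scan = list(p_threshold = 1e-4, q_cutoff = 0.5, pseudocount = 0.1,
                overlap_removal = FALSE),
    dataset = list(positive_class = NULL, min_peaks = 100L,
                   fractions = c(0.6, 0.2, 0.2)),
    model = list(mode = "binary", rounds = 10000L, learning_rate = 0.01,
                 max_depth = 6L, row_subsample = 0.5,
                 column_subsample = 0.5, early_stopping_rounds = 100L,
                 nthread = 1L),
    explain = list(split = "test"),
    assign = list(cells_per_type = 50L, min_peaks = 20L,
                  contamination = 0, dropout = 0, cap_per_type = 1000L),
    design = list(top_k = 5L, copies_per_motif = 2L, n_designs = 5L,
                  template_length = 260L),
    sweep = list(sizes = c(30L, 100L, 330L))
  )
}

#' @rdname default_pipeline_config
#' @param file YAML configuration path; entries override the defaults.
#' @export
read_pipeline_config <- function(file, seed = NULL) {
  user <- yaml::read_yaml(file)
  cfg <- default_pipeline_config(seed %||% user$seed %||% 1L)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_cfg(base[[nm]], over[[nm]])
      } else {
        over[[nm]]
      }
    }
    base
  }
  merge_cfg(cfg, user)
}

write_stage_manifest <- function(out_dir, stage, params, files) {
  files <- files[file.exists(files)]
  manifest <- list(stage = stage,
                   package_version =
                     as.character(utils::packageVersion("motifbag")),
                   parameters = params,
                   outputs = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest,
                       file.path(out_dir,
                                 sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

require_file <- function(path, stage_needed) {
  if (!file.exists(path)) {
    stop2("missing upstream artifact '", basename(path),
          "'; run the '", stage_needed, "' stage first")
  }
  path
}

#' Run the bag-of-motifs workflow
#'
#' Orchestrates the stages `simulate` (synthetic labeled CRE set +
#' accessibility matrix), `scan` (motif scanning + q-value filter),
#' `matrix` (count matrix), `train` (balanced assembly, split, boosted
#' trees), `eval` (held-out metrics), `explain` (Shapley attributions and
#' global ranking), `assign` (per-cell type assignment), `design` (SRE
#' construction from the top-ranked motifs) and `sweep` (positive-set
#' size titration). Every stage writes TSV/FASTA/JSON artifacts plus a
#' manifest with parameters, seeds and content hashes; identical
#' configurations reproduce identical artifacts.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or
#'   a YAML path.
#' @param stages Character vector of stages to run, in order.
#' @param out_dir Artifact directory (created if needed).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = c("simulate", "scan", "matrix",
                                    "train", "eval"),
                         out_dir = tempfile("motifbag_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  known <- c("simulate", "scan", "matrix", "train", "eval", "explain",
             "assign", "design", "sweep")
  bad <- setdiff(stages, known)
  if (length(bad)) stop2("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  state <- list(out_dir = out_dir)

  log_msg <- function(...) message("[motifbag] ", ...)

  if ("simulate" %in% stages) {
    sc <- config$simulate
    n_motifs <- sc$n_discriminative * length(sc$classes) + sc$n_decoy
    ms <- make_motif_set(n_motifs, sc$width_range, sc$concentration,
                         seed = seed)
    rate <- base::matrix(sc$decoy_rate, nrow = length(sc$classes),
                         ncol = n_motifs)
    for (ci in seq_along(sc$classes)) {
      for (mi in seq_len(n_motifs - sc$n_decoy)) {
        own <- ((mi - 1L) %/% sc$n_discriminative) + 1L
        rate[ci, mi] <- if (own == ci) sc$rate_target else
          sc$rate_background
      }
    }
    sim <- simulate_cre_dataset(sc$classes, sc$n_per_class, ms$motifs,
                                rate, sc$cre_width, sc$gc, seed = seed)
    write_fasta(sim$sequences, file.path(out_dir, "cres.fa"))
    utils::write.table(sim$labels, file.path(out_dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$implants, file.path(out_dir, "implants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(ms$meme, file.path(out_dir, "motifs.meme"))
    state$sim <- sim
    state$motifs <- ms$motifs
    disc <- vapply(ms$motifs[seq_len(n_motifs - sc$n_decoy)],
                   function(m) m$id, character(1))
    writeLines(disc, file.path(out_dir, "discriminative_motifs.txt"))
    write_stage_manifest(out_dir, "simulate", c(sc, seed = seed),
                         file.path(out_dir, c("cres.fa", "labels.tsv",
                                              "implants.tsv",
                                              "motifs.meme")))
    log_msg("simulate: ", length(sim$sequences), " CREs, ",
            n_motifs, " motifs")
  }

  if ("scan" %in% stages) {
    seqs <- if (!is.null(state$sim)) {
      state$sim$sequences
    } else {
      fa <- require_file(file.path(out_dir, "cres.fa"), "simulate")
      ss <- Biostrings::readDNAStringSet(fa)
      stats::setNames(toupper(as.character(ss)),
                      sub("\\s.*$", "", names(ss)))
    }
    motifs <- state$motifs %||%
      parse_meme(require_file(file.path(out_dir, "motifs.meme"),
                              "simulate"))$motifs
    pc <- config$scan
    hits <- scan_motifs(seqs, motifs, p_threshold = pc$p_threshold,
                        pseudocount = pc$pseudocount)
    n_raw <- nrow(hits)
    hits <- qvalue_filter(hits, pc$q_cutoff)
    log_msg("scan: ", n_raw, " raw hits, ", nrow(hits),
            " after q <= ", pc$q_cutoff)
    if (isTRUE(pc$overlap_removal)) {
      hits <- remove_overlapping_hits(hits, seed = seed)
      log_msg("scan: ", nrow(hits), " after overlap removal")
    }
    write_hits(hits, file.path(out_dir, "hits.tsv"))
    state$hits <- hits
    write_stage_manifest(out_dir, "scan", c(pc, seed = seed),
                         file.path(out_dir, "hits.tsv"))
  }

  if ("matrix" %in% stages) {
    hits <- state$hits %||%
      read_hits(require_file(file.path(out_dir, "hits.tsv"), "scan"))
    cre_ids <- if (!is.null(state$sim)) names(state$sim$sequences) else {
      fa <- require_file(file.path(out_dir, "cres.fa"), "simulate")
      sub("\\s.*$", "", names(Biostrings::readDNAStringSet(fa)))
    }
    motifs <- state$motifs %||%
      parse_meme(require_file(file.path(out_dir, "motifs.meme"),
                              "simulate"))$motifs
    state$motifs <- motifs
    counts <- build_count_matrix(hits, cre_ids,
                                 vapply(motifs, function(m) m$id,
                                        character(1)))
    write_count_matrix(counts, file.path(out_dir, "counts.tsv"))
    state$counts <- counts
    write_stage_manifest(out_dir, "matrix", list(seed = seed),
                         file.path(out_dir, "counts.tsv"))
    log_msg("matrix: ", nrow(counts), " x ", ncol(counts),
            " (total hits ", sum(counts), ")")
  }

  if (any(c("train", "eval", "explain", "design", "sweep") %in% stages)) {
    counts <- state$counts %||%
      read_count_matrix(require_file(file.path(out_dir, "counts.tsv"),
                                     "matrix"))
    labels <- state$sim$labels %||%
      read_labels(require_file(file.path(out_dir, "labels.tsv"),
                               "simulate"))
  }

  if ("train" %in% stages) {
    dc <- config$dataset
    mc <- config$model
    pos <- dc$positive_class %||% sort(unique(labels$label))[1]
    cfg <- bom_train_config(mc$mode, mc$rounds, mc$learning_rate,
                            mc$max_depth, mc$row_subsample,
                            mc$column_subsample,
                            mc$early_stopping_rounds, seed = seed,
                            nthread = mc$nthread)
    if (mc$mode == "binary") {
      bal <- assemble_balanced(counts, labels, pos, dc$min_peaks,
                               seed = seed)
      split <- split_dataset(nrow(bal$matrix), dc$fractions, seed = seed,
                             labels = bal$y)
      model <- train_bom(bal$matrix[split$train, , drop = FALSE],
                         bal$y[split$train],
                         bal$matrix[split$validation, , drop = FALSE],
                         bal$y[split$validation], cfg)
      state$dataset <- bal
    } else {
      y <- labels$label[match(rownames(counts), labels$name)]
      split <- split_dataset(nrow(counts), dc$fractions, seed = seed,
                             labels = y)
      model <- train_bom(counts[split$train, , drop = FALSE],
                         y[split$train],
                         counts[split$validation, , drop = FALSE],
                         y[split$validation], cfg)
      state$dataset <- list(matrix = counts, y = y)
    }
    state$split <- split
    state$model <- model
    save_bom_model(model, file.path(out_dir, "model"))
    jsonlite::write_json(split, file.path(out_dir, "split.json"),
                         digits = NA)
    write_stage_manifest(out_dir, "train",
                         list(dataset = dc, model = mc, seed = seed,
                              positive_class = pos),
                         file.path(out_dir, "model", "manifest.json"))
    log_msg("train: mode ", mc$mode, ", best iteration ",
            paste(model$best_iteration, collapse = ","))
  }

  if ("eval" %in% stages) {
    if (is.null(state$model)) stop2("'eval' requires the 'train' stage")
    ds <- state$dataset
    te <- state$split$test
    pred <- predict(state$model, ds$matrix[te, , drop = FALSE])
    if (state$model$config$mode == "binary") {
      rep_ <- confusion_metrics(pred$score, ds$y[te])
      write_metrics(rep_, file.path(out_dir, "metrics.json"))
      state$metrics <- rep_
      log_msg(sprintf(
        "eval: auROC %.3f auPR %.3f F1 %.3f MCC %.3f",
        rep_$metrics$auroc, rep_$metrics$aupr, rep_$metrics$f1,
        rep_$metrics$mcc))
    } else {
      acc <- mean(pred$label == ds$y[te])
      jsonlite::write_json(list(accuracy = acc),
                           file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      state$metrics <- list(accuracy = acc)
      log_msg(sprintf("eval: multiclass accuracy %.3f", acc))
    }
    write_stage_manifest(out_dir, "eval", list(seed = seed),
                         file.path(out_dir, "metrics.json"))
  }

  if ("explain" %in% stages) {
    if (is.null(state$model)) stop2("'explain' requires the 'train' stage")
    ds <- state$dataset
    rows <- switch(config$explain$split %||% "test",
                   test = state$split$test,
                   validation = state$split$validation,
                   train = state$split$train,
                   all = seq_len(nrow(ds$matrix)))
    expl <- explain(state$model, ds$matrix[rows, , drop = FALSE])
    ranking <- rank_motifs(expl)
    utils::write.table(ranking, file.path(out_dir, "motif_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$explanation <- expl
    state$ranking <- ranking
    write_stage_manifest(out_dir, "explain",
                         list(split = config$explain$split, seed = seed),
                         file.path(out_dir, "motif_ranking.tsv"))
    log_msg("explain: top motif ", ranking$motif[1])
  }

  if ("assign" %in% stages) {
    ac <- config$assign
    counts <- state$counts %||%
      read_count_matrix(require_file(file.path(out_dir, "counts.tsv"),
                                     "matrix"))
    labels <- (if (!is.null(state$sim)) state$sim$labels else NULL) %||%
      read_labels(require_file(file.path(out_dir, "labels.tsv"),
                               "simulate"))
    y <- labels$label[match(rownames(counts), labels$name)]
    mc_cfg <- bom_train_config("multiclass",
                               rounds = config$model$rounds,
                               learning_rate = config$model$learning_rate,
                               max_depth = config$model$max_depth,
                               row_subsample = config$model$row_subsample,
                               column_subsample =
                                 config$model$column_subsample,
                               early_stopping_rounds =
                                 config$model$early_stopping_rounds,
                               seed = seed, nthread = config$model$nthread)
    split <- split_dataset(nrow(counts), config$dataset$fractions,
                           seed = seed, labels = y)
    mc_model <- train_bom(counts[split$train, , drop = FALSE],
                          y[split$train],
                          counts[split$validation, , drop = FALSE],
                          y[split$validation], mc_cfg)
    marker_rows <- split$test
    expl <- explain(mc_model, counts[marker_rows, , drop = FALSE])
    peaks_by_type <- split(rownames(counts)[marker_rows], y[marker_rows])
    access <- simulate_cell_accessibility(
      sort(unique(y)), ac$cells_per_type, peaks_by_type,
      ac$contamination, ac$dropout, seed = seed)
    access <- downsample_cells(access, ac$cap_per_type, seed = seed)
    agg <- aggregate_cell_shap(expl, access, min_peaks = ac$min_peaks)
    asg <- assign_cell_types(agg)
    asg$true_type <- agg$cell_types[asg$cell]
    utils::write.table(asg, file.path(out_dir, "cell_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$assignments <- asg
    write_stage_manifest(out_dir, "assign", c(ac, seed = seed),
                         file.path(out_dir, "cell_assignments.tsv"))
    log_msg(sprintf("assign: accuracy %.3f over %d cells",
                    mean(asg$predicted == asg$true_type), nrow(asg)))
  }

  if ("design" %in% stages) {
    if (is.null(state$ranking)) stop2("'design' requires 'explain'")
    gc_frac <- config$simulate$gc %||% 0.41
    dcfg <- config$design
    top_ids <- select_top_motifs(state$ranking, dcfg$top_k)
    motifs <- state$motifs[match(
      top_ids, vapply(state$motifs, function(m) m$id, character(1)))]
    template <- with_rng_seed(seed + 1L, paste(
      sample(DNA_BASES, dcfg$template_length, replace = TRUE,
             prob = c((1 - gc_frac) / 2, gc_frac / 2, gc_frac / 2,
                      (1 - gc_frac) / 2)), collapse = ""))
    sre <- design_sres(template, motifs, dcfg$copies_per_motif,
                       dcfg$n_designs, seed = seed)
    write_fasta(sre$designs, file.path(out_dir, "sre_designs.fa"))
    utils::write.table(sre$implants,
                       file.path(out_dir, "sre_implants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$sre <- sre
    write_stage_manifest(out_dir, "design", c(dcfg, seed = seed),
                         file.path(out_dir, c("sre_designs.fa",
                                              "sre_implants.tsv")))
    log_msg("design: ", length(sre$designs), " SREs of length ",
            nchar(sre$designs[1]))
  }

  if ("sweep" %in% stages) {
    dc <- config$dataset
    mc <- config$model
    pos <- dc$positive_class %||% sort(unique(labels$label))[1]
    pos_names <- labels$name[labels$label == pos]
    res <- list()
    for (nsub in config$sweep$sizes) {
      sub_names <- with_rng_seed(seed + nsub, {
        pos_names[sample.int(length(pos_names), min(nsub,
                                                    length(pos_names)))]
      })
      keep <- labels$label != pos | labels$name %in% sub_names
      sub_labels <- labels[keep, , drop = FALSE]
      bal <- assemble_balanced(counts, sub_labels, pos,
                               min_peaks = min(dc$min_peaks, nsub),
                               seed = seed)
      split <- split_dataset(nrow(bal$matrix), dc$fractions,
                             seed = seed, labels = bal$y)
      cfg <- bom_train_config("binary", mc$rounds, mc$learning_rate,
                              mc$max_depth, mc$row_subsample,
                              mc$column_subsample,
                              mc$early_stopping_rounds, seed = seed,
                              nthread = mc$nthread)
      model <- train_bom(bal$matrix[split$train, , drop = FALSE],
                         bal$y[split$train],
                         bal$matrix[split$validation, , drop = FALSE],
                         bal$y[split$validation], cfg)
      pred <- predict(model, bal$matrix[split$test, , drop = FALSE])
      rep_ <- confusion_metrics(pred$score, bal$y[split$test])
      dir.create(file.path(out_dir, "sweep"), showWarnings = FALSE)
      write_metrics(rep_, file.path(out_dir, "sweep",
                                    sprintf("metrics_n%d.json", nsub)))
      res[[as.character(nsub)]] <- rep_$metrics
      log_msg(sprintf("sweep n=%d: MCC %.3f", nsub, rep_$metrics$mcc))
    }
    state$sweep <- res
    write_stage_manifest(out_dir, "sweep",
                         c(config$sweep, seed = seed),
                         list.files(file.path(out_dir, "sweep"),
                                    full.names = TRUE))
  }

  invisible(state)
}
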