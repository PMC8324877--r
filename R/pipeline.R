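#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: discretization
#' thresholds, history lengths, null replicate counts, significance
#' level and seed.
#'
#' @param subjects Either a list of regions x time numeric matrices
#'   (in-memory input) or `NULL` when `input_dir` is given.
#' @param input_dir Directory of per-subject series tables
#'   ([write_series()] layout); every `*.tsv` file is one subject.
#' @param fd_dir Optional directory of one-column framewise-displacement
#'   tables named like the subject files; when present, scrubbing is
#'   applied before discretization.
#' @param thresholds Strictly increasing positive S.D. thresholds
#'   (default `c(0.25, 0.5, 0.75, 1)`).
#' @param n_null_te Reshuffling replicates for the rule-selection null
#'   (default 100).
#' @param n_null_network Randomization replicates for the network
#'   indexes (default 100).
#' @param alpha Significance level (default 0.05).
#' @param trend Trend requirement passed to [rule_selection()].
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param out_dir Output directory for the report bundle (`NULL` keeps
#'   everything in memory).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(subjects = NULL, input_dir = NULL, fd_dir = NULL,
                            thresholds = c(0.25, 0.5, 0.75, 1),
                            n_null_te = 100L, n_null_network = 100L,
                            alpha = 0.05, trend = "both", seed = 1L,
                            out_dir = NULL) {
  if (is.null(subjects) && is.null(input_dir))
    stop("either subjects or input_dir must be given")
  if (any(thresholds <= 0) || any(diff(thresholds) <= 0))
    stop("thresholds must be positive and strictly increasing")
  if (n_null_te < 1L || n_null_network < 1L)
    stop("replicate counts must be >= 1")
  structure(list(subjects = subjects, input_dir = input_dir, fd_dir = fd_dir,
                 thresholds = thresholds, history_k = 1L, history_l = 1L,
                 n_null_te = as.integer(n_null_te),
                 n_null_network = as.integer(n_null_network),
                 alpha = alpha, trend = trend, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Discretize -> rule-resolved local TE -> reshuffling null and rule
#' selection -> functional layers -> three-level multiplex -> layer
#' descriptors, reciprocity/multireciprocity, triad census with
#' significance, centrality classes and modularity.  Identical config
#' and seed give identical outputs; when `out_dir` is set, the numeric
#' tables are persisted along with a manifest listing each artifact and
#' its content hash.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit stage-level progress messages (default `TRUE`).
#' @return A list of class `pipeline_report` with elements `tensor`,
#'   `null`, `selection`, `trend`, `correlation`, `clustering`,
#'   `taxonomy`, `net` (mean three-level multiplex), `subject_nets`,
#'   `descriptors`, `reciprocity`, `triads`, `centrality`, `modularity`,
#'   `config`, and `manifest` when written to disk.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[teplex] ", sprintf(...))

  stage <- "input"
  res <- tryCatch({
    subjects <- config$subjects
    if (is.null(subjects)) {
      files <- sort(list.files(config$input_dir, pattern = "\\.tsv$",
                               full.names = TRUE))
      if (length(files) == 0L)
        stop("no subject tables (*.tsv) in ", config$input_dir)
      subjects <- lapply(files, read_series)
      names(subjects) <- sub("\\.tsv$", "", basename(files))
    }
    if (is.null(names(subjects)))
      names(subjects) <- paste0("S", seq_along(subjects))
    say("loaded %d subject(s), %d regions x %d time points",
        length(subjects), nrow(subjects[[1]]), ncol(subjects[[1]]))

    stage <- "scrubbing"
    if (!is.null(config$fd_dir)) {
      for (nm in names(subjects)) {
        fd_file <- file.path(config$fd_dir, paste0(nm, ".tsv"))
        if (!file.exists(fd_file)) stop("missing FD table: ", fd_file)
        fd <- utils::read.table(fd_file, header = FALSE)[[1L]]
        mask <- scrub_fd(fd)
        if (mask$subject_excluded) {
          say("subject %s excluded by scrubbing (%d bad scans)", nm,
              mask$n_bad)
          subjects[[nm]] <- NULL
        } else if (mask$n_bad > 0) {
          subjects[[nm]] <- apply_scrub(subjects[[nm]], mask)
        }
      }
      if (length(subjects) == 0L) stop("all subjects excluded by scrubbing")
    }

    stage <- "rule tensor"
    say("building rule tensor at %d threshold(s)", length(config$thresholds))
    tensor <- build_rule_tensor(subjects, thresholds = config$thresholds)

    stage <- "reshuffling null"
    say("reshuffling null: %d replicates", config$n_null_te)
    null <- reshuffle_null(subjects, n_replicates = config$n_null_te,
                           seed = sub_seed(config$seed, 1),
                           thresholds = max(config$thresholds),
                           keep_values = FALSE)

    stage <- "rule selection"
    sel <- rule_selection(tensor, null, alpha = config$alpha,
                          trend = config$trend)
    say("selected %d rule(s): %s", nrow(sel$selected),
        paste(sel$selected$id, collapse = " "))

    stage <- "rule classification"
    tax <- rule_taxonomy()
    corr <- clus <- NULL
    if (nrow(sel$selected) >= 2L) {
      corr <- rule_correlation(tensor, sel$selected)
      if (!anyNA(corr)) clus <- cluster_rules(corr)
    }

    stage <- "multiplex assembly"
    alpha_net <- build_rule_layers(tensor)
    net <- add_hierarchy(alpha_net)
    subject_alpha <- build_rule_layers(tensor,
                                       subject_reduction = "per-subject")
    subject_nets <- lapply(subject_alpha, add_hierarchy)
    desc <- layer_descriptors(subject_nets)

    stage <- "reciprocity"
    say("reciprocity / multireciprocity (%d null replicates)",
        config$n_null_network)
    recip <- multireciprocity_table(subject_nets,
                                    n_null = config$n_null_network,
                                    null_method = "in_strength",
                                    seed = sub_seed(config$seed, 2),
                                    alpha = config$alpha)

    stage <- "triad census"
    say("triad census and significance")
    pats <- list()
    for (lev in unique(net$level)) {
      lys <- names(net$layers)[net$level == lev]
      for (ord in 0:2) {
        p <- enumerate_triad_patterns(lys, ord)
        if (nrow(p)) { p$level <- lev; pats[[length(pats) + 1L]] <- p }
      }
    }
    pats <- do.call(rbind, pats)
    if (length(subject_nets) >= 2L) {
      # subgraphs are global (per-subject) indexes: score each subject's
      # net, pool per-subject randomizations as the null
      triads <- triad_group_significance(
        subject_nets, pats,
        n_null = max(1L, config$n_null_network %/% length(subject_nets)),
        null_method = "in_strength", seed = sub_seed(config$seed, 3),
        alpha = config$alpha)
    } else {
      triads <- subgraph_significance(net, pats,
                                      n_replicates = config$n_null_network,
                                      null_method = "permute",
                                      seed = sub_seed(config$seed, 3),
                                      alpha = config$alpha)
    }
    triads$level <- pats$level

    stage <- "centrality"
    centrality <- lapply(stats::setNames(nm = unique(net$level)),
                         function(lev) central_nodes(net, level = lev))

    stage <- "modularity"
    say("modularity per layer (%d null replicates)", config$n_null_network)
    modularity <- lapply(stats::setNames(nm = names(net$layers)),
      function(nm) {
        W <- net$layers[[nm]]
        if (sum(W) == 0) return(NULL)
        modularity_significance(W, n_replicates = config$n_null_network,
                                randomization = "permute",
                                seed = sub_seed(config$seed, 4))
      })

    report <- structure(
      list(tensor = tensor, null = null, selection = sel,
           trend = sel$trend_stats, correlation = corr, clustering = clus,
           taxonomy = tax, net = net, subject_nets = subject_nets,
           descriptors = desc, reciprocity = recip, triads = triads,
           centrality = centrality, modularity = modularity,
           config = config),
      class = "pipeline_report")

    if (!is.null(config$out_dir)) {
      stage <- "report writing"
      report$manifest <- write_report(report, config$out_dir)
    }
    report
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  say("done")
  invisible(res)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  %d subject(s), %d selected rule(s)\n",
              dim(x$tensor)[1L], nrow(x$selection$selected)))
  cat(sprintf("  multiplex: %d layers / %d nodes\n",
              length(x$net$layers), length(x$net$nodes)))
  invisible(x)
}

# Persist the numeric tables of a report and return the manifest
# (relative path + md5 content hash per artifact).
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }
  wr_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    paths[[length(paths) + 1L]] <<- p
  }

  st <- report$trend
  wr_tsv(data.frame(rule = rownames(st$totals), st$totals,
                    check.names = FALSE), "rule-te-totals.tsv")
  wr_tsv(data.frame(rule = rownames(st$mse), st$mse, check.names = FALSE),
         "rule-te-mse.tsv")
  wr_tsv(report$selection$subject_table, "rule-subject-table.tsv")
  wr_json(list(selected = report$selection$selected$id,
               excluded_subjects = report$selection$excluded_subjects,
               alpha = report$selection$alpha,
               n_tests = report$selection$n_tests),
          "rule-selection.json")
  if (!is.null(report$correlation))
    wr_tsv(data.frame(rule = rownames(report$correlation),
                      report$correlation, check.names = FALSE),
           "rule-correlation.tsv")
  wr_json(report$taxonomy, "rule-taxonomy.json")
  write_multiplex(report$net, file.path(out_dir, "multiplex"))
  paths <- c(paths, list.files(file.path(out_dir, "multiplex"),
                               full.names = TRUE))
  wr_tsv(report$descriptors, "layer-descriptors.tsv")
  wr_tsv(report$reciprocity, "reciprocity.tsv")
  wr_tsv(report$triads, "triad-scores.tsv")
  for (lev in names(report$centrality))
    wr_tsv(report$centrality[[lev]]$classes,
           sprintf("centrality-%s.tsv", lev))
  mods <- report$modularity[!vapply(report$modularity, is.null, TRUE)]
  wr_tsv(data.frame(layer = names(mods),
                    Q = vapply(mods, `[[`, 0, "Q"),
                    null_mean = vapply(mods, `[[`, 0, "null_mean"),
                    null_sd = vapply(mods, `[[`, 0, "null_sd"),
                    p = vapply(mods, `[[`, 0, "p_value")),
         "modularity.tsv")
  for (nm in names(mods))
    wr_tsv(data.frame(node = names(mods[[nm]]$labels),
                      community = unname(mods[[nm]]$labels)),
           sprintf("communities-%s.tsv", nm))

  norm <- normalizePath(paths)
  base <- normalizePath(out_dir)
  manifest <- data.frame(
    file = substring(norm, nchar(base) + 2L),
    md5 = unname(tools::md5sum(paths)), stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Simulate a demo dataset of coupled ternary dynamics
#'
#' Generates per-subject continuous series from planted rule-driven
#' ternary dynamics: the eight core rules are planted on distinct node
#' pairs with the given coupling probability, states are rendered
#' continuous with [wrap_continuous()], and (optionally) the tables are
#' written to disk.  The defaults mirror the reference acquisition
#' scale: 10 subjects, 90 regions, 240 volumes.
#'
#' @param n_subjects,n_nodes,n_time Dataset dimensions.
#' @param baseline Baseline state probabilities over (-1, 0, 1); the
#'   default `c(0.2, 0.6, 0.2)` keeps suprathreshold events sparse, as
#'   after 1-S.D. ternarization of resting BOLD.
#' @param coupling_prob Probability that a planted rule fires (default
#'   0.9).
#' @param amplitude_sd Noise S.D. of the continuous wrapper (default
#'   0.25, so that 1-S.D. ternarization recovers most planted events
#'   while lower thresholds remain noisy).
#' @param seed Integer seed.
#' @param out_dir Optional output directory ([write_series()] tables).
#' @return A named list of continuous subject matrices (invisibly the
#'   written paths as attribute `paths` when `out_dir` is set), with the
#'   planted couplings as attribute `couplings`.
#' @export
simulate_dataset <- function(n_subjects = 10L, n_nodes = 90L, n_time = 240L,
                             baseline = c(0.2, 0.6, 0.2),
                             coupling_prob = 0.9, amplitude_sd = 0.25,
                             seed = 1L, out_dir = NULL) {
  tax <- rule_taxonomy()
  n_pairs <- min(5L * 8L, n_nodes %/% 2L)   # up to 5 planted pairs per rule
  cps <- lapply(seq_len(n_pairs), function(i) {
    k <- (i - 1L) %% 8L + 1L
    coupling(2L * i - 1L, 2L * i,
             c(tax$a[k], tax$b[k], tax$bnext[k]), coupling_prob)
  })
  subjects <- lapply(seq_len(n_subjects), function(s) {
    cfg <- generator_config(n_nodes, n_time, baseline = baseline,
                            couplings = cps,
                            seed = sub_seed(seed, 100 + s))
    wrap_continuous(generate_ternary_dynamics(cfg), amplitude_sd,
                    seed = sub_seed(seed, 200 + s))
  })
  names(subjects) <- sprintf("sub%02d", seq_len(n_subjects))
  attr(subjects, "couplings") <- cps
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(subjects), function(nm)
      write_series(subjects[[nm]], file.path(out_dir,
                                             paste0(nm, ".tsv"))), "")
    attr(subjects, "paths") <- paths
  }
  subjects
}

#' Run the bundled synthetic demo end to end
#'
#' Simulates the reference-scale dataset (10 subjects, 90 regions, 240
#' time points) with the eight core rules planted on 40 node pairs,
#' then runs the full pipeline on it.  The demo uses the null-based
#' group test without the threshold-trend gate (`trend = "none"`): the
#' synthetic generator's memoryless background does not reproduce the
#' threshold-trend behaviour of resting BOLD, so the trend flags are
#' uninformative on simulated data.
#'
#' @param seed Integer master seed (default 1).
#' @param out_dir Optional report directory.
#' @param n_subjects,n_nodes,n_time Dataset dimensions (defaults 10,
#'   90, 240).
#' @param n_null_te,n_null_network Replicate counts (default 50 each).
#' @param verbose Stage messages (default `TRUE`).
#' @return The [run_pipeline()] report, invisibly.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, n_subjects = 10L,
                     n_nodes = 90L, n_time = 240L, n_null_te = 50L,
                     n_null_network = 50L, verbose = TRUE) {
  subjects <- simulate_dataset(n_subjects = n_subjects, n_nodes = n_nodes,
                               n_time = n_time, seed = seed)
  cfg <- pipeline_config(subjects = subjects, trend = "none",
                         n_null_te = n_null_te,
                         n_null_network = n_null_network,
                         seed = seed, out_dir = out_dir)
  run_pipeline(cfg, verbose = verbose)
}
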