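# Synthetic association-table generator with a ground-truth ledger.
#
# Emulates the five input tables the pipeline consumes: verified
# miRNA-target pairs (with decoy rows targeting non-disease genes), a
# disease gene list, TF binding-site hit tables for nested promoter windows
# (every 1000nt hit also appears as a 5000nt hit, so window nesting holds by
# construction), TcoF-TF interaction pairs with a confidence label, and a
# background PPI table that also covers proteins the construction step must
# exclude. Binding-site scores are drawn from configurable ranges straddling
# the 0.9 filter threshold so the score filter is exercised. Motifs can be
# planted on top of the sampled background; the ledger records the final
# ground truth (realized census per window, planted motif lists, per-table
# row counts) so every downstream stage can be checked exactly.

#' Configuration for the synthetic-data generator
#'
#' Per-miRNA target counts follow 1 + Geometric (heavy-tailed, emulating
#' hub targets that attract many miRNAs); every disease gene in the target
#' pool is guaranteed at least one targeting miRNA so realized role counts
#' equal the configured counts. A configurable fraction of TFs doubles as
#' disease targets (role overlap). Binding-site presence is Bernoulli per
#' (TF, miRNA promoter) pair, with proximal (1000nt) hits a subset of the
#' 5000nt hits.
#'
#' @param n_mirnas,n_targets,n_tfs,n_tcofs,n_nondisease_genes entity counts;
#'   `n_targets` is the size of the disease gene pool, of which
#'   `round(tf_target_overlap * n_tfs)` are TFs that double as targets.
#' @param mean_targets_per_mirna mean verified disease targets per miRNA
#'   (>= 1).
#' @param tf_hit_prob probability that a TF has a binding-site hit (any
#'   score) within 1000nt of a given miRNA promoter.
#' @param tf_hit_prob_5000 same for the 5000nt window; must be >=
#'   `tf_hit_prob` (nesting).
#' @param ppi_density probability of a background interaction per unordered
#'   protein pair.
#' @param mean_tfs_per_tcof mean number of high-confidence TF partners per
#'   TcoF (>= 1).
#' @param tf_target_overlap fraction of TFs that are also disease targets.
#' @param frac_hits_below_threshold fraction of binding-site hits whose
#'   scores fall below the 0.9 filter threshold.
#' @param score_range_pass,score_range_fail uniform ranges for passing
#'   (both scores >= 0.9) and failing hit scores.
#' @param nondisease_target_prob probability per miRNA of one decoy row
#'   targeting a non-disease gene (dropped at construction).
#' @param low_conf_tcof_prob probability per TcoF of one decoy
#'   low-confidence interaction row (dropped at construction).
#' @param n_planted_self_loops,n_planted_feedback_loops motifs planted on
#'   top of the background; infeasible requests error.
#' @param seed integer seed making generation fully deterministic.
#' @return A validated list of class `ocm_genconfig`.
#' @export
generator_config <- function(n_mirnas = 20L, n_targets = 15L, n_tfs = 10L,
                             n_tcofs = 5L, n_nondisease_genes = 10L,
                             mean_targets_per_mirna = 2,
                             tf_hit_prob = 0.15, tf_hit_prob_5000 = 0.3,
                             ppi_density = 0.02, mean_tfs_per_tcof = 2,
                             tf_target_overlap = 0.1,
                             frac_hits_below_threshold = 0.3,
                             score_range_pass = c(0.9, 1),
                             score_range_fail = c(0.5, 0.9),
                             nondisease_target_prob = 0.25,
                             low_conf_tcof_prob = 0.2,
                             n_planted_self_loops = 0L,
                             n_planted_feedback_loops = 0L,
                             seed = 1L) {
  cfg <- structure(as.list(environment()), class = "ocm_genconfig")
  counts <- c(cfg$n_mirnas, cfg$n_targets, cfg$n_tfs, cfg$n_tcofs,
              cfg$n_nondisease_genes, cfg$n_planted_self_loops,
              cfg$n_planted_feedback_loops)
  if (any(counts < 0)) stop("counts must be >= 0")
  probs <- c(cfg$tf_hit_prob, cfg$tf_hit_prob_5000, cfg$ppi_density,
             cfg$tf_target_overlap, cfg$frac_hits_below_threshold,
             cfg$nondisease_target_prob, cfg$low_conf_tcof_prob)
  if (any(probs < 0 | probs > 1)) stop("densities/fractions must be in [0, 1]")
  if (cfg$tf_hit_prob > cfg$tf_hit_prob_5000) {
    stop("tf_hit_prob must not exceed tf_hit_prob_5000 (window nesting)")
  }
  if (cfg$mean_targets_per_mirna < 1) stop("mean_targets_per_mirna must be >= 1")
  if (cfg$mean_tfs_per_tcof < 1) stop("mean_tfs_per_tcof must be >= 1")
  if (min(cfg$score_range_pass) < 0.9 || max(cfg$score_range_pass) > 1 ||
      min(cfg$score_range_fail) < 0 || max(cfg$score_range_fail) > 0.9) {
    stop("score ranges must straddle the 0.9 threshold ",
         "(pass within [0.9, 1], fail within [0, 0.9])")
  }
  n_overlap <- round(cfg$tf_target_overlap * cfg$n_tfs)
  if (n_overlap > cfg$n_targets) stop("more overlap TFs than target-pool slots")
  if (cfg$n_planted_self_loops > min(cfg$n_mirnas, n_overlap)) {
    stop("infeasible plant request: self loops need ",
         "min(n_mirnas, overlap TFs) >= n_planted_self_loops")
  }
  if (cfg$n_planted_feedback_loops >
      min(cfg$n_mirnas, cfg$n_tfs, cfg$n_targets - n_overlap)) {
    stop("infeasible plant request: feedback loops need enough distinct ",
         "miRNAs, TFs and non-TF disease genes")
  }
  cfg
}

#' Generator configuration at the published networks' scale
#'
#' Counts match the published role counts (162 miRNAs, 131 disease targets,
#' 244 TFs of which 19 double as targets, 140 TcoFs) and densities are set so
#' the expected edge counts approximate the published census (434 targeting
#' edges; 5327 / 14720 regulation edges in the 1000 / 5000nt windows; ~4400
#' PPI edges).
#'
#' @param seed integer seed.
#' @return An `ocm_genconfig`.
#' @export
published_scale_config <- function(seed = 1L) {
  n_tfs <- 244L
  n_mirnas <- 162L
  frac_fail <- 0.25
  generator_config(
    n_mirnas = n_mirnas, n_targets = 131L, n_tfs = n_tfs, n_tcofs = 140L,
    n_nondisease_genes = 60L,
    mean_targets_per_mirna = 434 / n_mirnas,
    tf_hit_prob = 5327 / (n_tfs * n_mirnas) / (1 - frac_fail),
    tf_hit_prob_5000 = 14720 / (n_tfs * n_mirnas) / (1 - frac_fail),
    ppi_density = 3960 / choose(496, 2),
    mean_tfs_per_tcof = 3,
    tf_target_overlap = 19 / n_tfs,
    frac_hits_below_threshold = frac_fail,
    seed = seed)
}

sample_distinct_pairs <- function(pool, m) {
  # sample m distinct unordered pairs (i < j) from choose(P, 2)
  p <- length(pool)
  total <- p * (p - 1) / 2
  m <- min(m, total)
  if (m == 0) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- sort(sample.int(total, m))
  # unrank: pair index -> (i, j) with i < j, row-major over i
  i <- findInterval(idx - 1, cumsum((p - 1):1), left.open = FALSE) + 1L
  offset <- c(0, cumsum((p - 1):1))[i]
  j <- i + (idx - offset)
  data.frame(protein_a = pool[i], protein_b = pool[j],
             stringsAsFactors = FALSE)
}

#' Generate synthetic association tables and their ground-truth ledger
#'
#' @param config an `ocm_genconfig` from [generator_config()] or
#'   [published_scale_config()].
#' @return List with elements `tables` (named list of the five data.frames:
#'   `mirna_targets`, `disease_genes`, `tf_hits`, `tcof_pairs`,
#'   `ppi_pairs`), `ledger` (ground truth: per-window expected census,
#'   planted motif tables, per-table row counts, TFBS filter pass rate) and
#'   `config`. Deterministic given `config$seed`; the caller's RNG state is
#'   untouched.
#' @export
generate_tables <- function(config) {
  stopifnot(inherits(config, "ocm_genconfig"))
  with_seed(config$seed, generate_tables_impl(config))
}

generate_tables_impl <- function(cfg) {
  n_overlap <- round(cfg$tf_target_overlap * cfg$n_tfs)
  mirnas <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))
  tfs <- sprintf("TF-%03d", seq_len(cfg$n_tfs))
  overlap_tfs <- tfs[seq_len(n_overlap)]
  pure_genes <- sprintf("GENE-%03d", seq_len(cfg$n_targets - n_overlap))
  target_pool <- c(pure_genes, overlap_tfs)
  tcofs <- sprintf("TCOF-%03d", seq_len(cfg$n_tcofs))
  ndgs <- sprintf("NDG-%03d", seq_len(cfg$n_nondisease_genes))

  # --- planted motif assignments (ids fixed before background sampling) ---
  psl <- data.frame(
    mirna = mirnas[seq_len(cfg$n_planted_self_loops)],
    tf = overlap_tfs[seq_len(cfg$n_planted_self_loops)],
    stringsAsFactors = FALSE)
  pfl <- data.frame(
    tf = rev(tfs)[seq_len(cfg$n_planted_feedback_loops)],
    mirna = rev(mirnas)[seq_len(cfg$n_planted_feedback_loops)],
    target = rev(pure_genes)[seq_len(cfg$n_planted_feedback_loops)],
    stringsAsFactors = FALSE)

  # --- verified miRNA -> disease-target edges (heavy-tailed out-degree) ---
  p_geom <- 1 / cfg$mean_targets_per_mirna
  k <- pmin(1L + rgeom(cfg$n_mirnas, p_geom), length(target_pool))
  targeting <- do.call(rbind, lapply(seq_len(cfg$n_mirnas), function(i) {
    data.frame(mirna_id = mirnas[i],
               target_id = sample(target_pool, k[i]),
               stringsAsFactors = FALSE)
  }))
  uncovered <- setdiff(target_pool, targeting$target_id)
  if (length(uncovered)) {
    targeting <- rbind(targeting, data.frame(
      mirna_id = sample(mirnas, length(uncovered), replace = TRUE),
      target_id = uncovered, stringsAsFactors = FALSE))
  }
  if (nrow(psl)) {
    targeting <- rbind(targeting, data.frame(
      mirna_id = psl$mirna, target_id = psl$tf, stringsAsFactors = FALSE))
  }
  if (nrow(pfl)) {
    targeting <- rbind(targeting, data.frame(
      mirna_id = pfl$mirna, target_id = pfl$target, stringsAsFactors = FALSE))
  }
  targeting <- unique(targeting)
  decoy_sel <- cfg$n_nondisease_genes > 0 &
    runif(cfg$n_mirnas) < cfg$nondisease_target_prob
  decoys <- if (any(decoy_sel)) {
    data.frame(mirna_id = mirnas[decoy_sel],
               target_id = sample(ndgs, sum(decoy_sel), replace = TRUE),
               stringsAsFactors = FALSE)
  }
  mirna_targets <- unique(rbind(targeting, decoys))
  mirna_targets <- mirna_targets[order(mirna_targets$mirna_id,
                                       mirna_targets$target_id), ]

  # --- TFBS hits on the two nested promoter windows ---
  grid <- expand.grid(tf_id = tfs, mirna_id = mirnas,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  np <- nrow(grid)
  hit5 <- runif(np) < cfg$tf_hit_prob_5000
  cond <- if (cfg$tf_hit_prob_5000 > 0) {
    cfg$tf_hit_prob / cfg$tf_hit_prob_5000
  } else 0
  hit1 <- hit5 & runif(np) < cond
  pass <- runif(np) >= cfg$frac_hits_below_threshold
  core <- ifelse(pass,
                 runif(np, cfg$score_range_pass[1], cfg$score_range_pass[2]),
                 runif(np, cfg$score_range_fail[1], cfg$score_range_fail[2]))
  matx <- ifelse(pass,
                 runif(np, cfg$score_range_pass[1], cfg$score_range_pass[2]),
                 runif(np, cfg$score_range_fail[1], cfg$score_range_fail[2]))
  planted_pairs <- rbind(
    data.frame(tf_id = psl$tf, mirna_id = psl$mirna,
               stringsAsFactors = FALSE),
    data.frame(tf_id = pfl$tf, mirna_id = pfl$mirna,
               stringsAsFactors = FALSE))
  if (nrow(planted_pairs)) {
    sel <- paste(grid$tf_id, grid$mirna_id) %in%
      paste(planted_pairs$tf_id, planted_pairs$mirna_id)
    hit5[sel] <- TRUE
    hit1[sel] <- TRUE
    pass[sel] <- TRUE
    core[sel] <- runif(sum(sel), cfg$score_range_pass[1],
                       cfg$score_range_pass[2])
    matx[sel] <- runif(sum(sel), cfg$score_range_pass[1],
                       cfg$score_range_pass[2])
  }
  tf_hits <- rbind(
    data.frame(grid[hit5, ], core_score = core[hit5],
               matrix_score = matx[hit5],
               window_nt = rep(5000L, sum(hit5))),
    data.frame(grid[hit1, ], core_score = core[hit1],
               matrix_score = matx[hit1],
               window_nt = rep(1000L, sum(hit1))))
  tf_hits <- tf_hits[order(tf_hits$tf_id, tf_hits$mirna_id,
                           tf_hits$window_nt), ]
  rownames(tf_hits) <- NULL

  # --- TcoF-TF interactions ---
  tcof_pairs <- do.call(rbind, lapply(tcofs, function(cf) {
    nl <- min(1L + rpois(1L, cfg$mean_tfs_per_tcof - 1), cfg$n_tfs)
    high <- data.frame(tcof_id = cf, tf_id = sample(tfs, nl),
                       confidence = "high", stringsAsFactors = FALSE)
    if (runif(1) < cfg$low_conf_tcof_prob) {
      rest <- setdiff(tfs, high$tf_id)
      if (length(rest)) {
        high <- rbind(high, data.frame(tcof_id = cf,
                                       tf_id = sample(rest, 1L),
                                       confidence = "low",
                                       stringsAsFactors = FALSE))
      }
    }
    high
  }))
  if (is.null(tcof_pairs)) {
    tcof_pairs <- data.frame(tcof_id = character(), tf_id = character(),
                             confidence = character(),
                             stringsAsFactors = FALSE)
  }
  tcof_pairs <- tcof_pairs[order(tcof_pairs$tcof_id, tcof_pairs$tf_id), ]
  rownames(tcof_pairs) <- NULL

  # --- background PPIs over all proteins (retained or not) ---
  all_proteins <- unique(c(pure_genes, tfs, tcofs, ndgs))
  total_pairs <- choose(length(all_proteins), 2)
  n_ppi <- rbinom(1L, total_pairs, cfg$ppi_density)
  ppi <- sample_distinct_pairs(all_proteins, n_ppi)
  if (nrow(pfl)) {
    ppi <- rbind(ppi, data.frame(protein_a = pfl$target, protein_b = pfl$tf,
                                 stringsAsFactors = FALSE))
  }
  flip <- ppi$protein_a > ppi$protein_b
  tmp <- ppi$protein_a[flip]
  ppi$protein_a[flip] <- ppi$protein_b[flip]
  ppi$protein_b[flip] <- tmp
  ppi <- unique(ppi)
  ppi <- ppi[order(ppi$protein_a, ppi$protein_b), ]
  rownames(ppi) <- NULL

  tables <- list(
    mirna_targets = mirna_targets,
    disease_genes = data.frame(gene_id = sort(target_pool),
                               stringsAsFactors = FALSE),
    tf_hits = tf_hits,
    tcof_pairs = tcof_pairs,
    ppi_pairs = ppi)

  ledger <- build_ledger(cfg, tables, psl, pfl, target_pool)
  list(tables = tables, ledger = ledger, config = cfg)
}

# Ground-truth bookkeeping mirroring the construction rules, computed from
# the generator's own intermediates rather than via build_network().
build_ledger <- function(cfg, tables, psl, pfl, target_pool) {
  hits <- tables$tf_hits
  passing <- hits[hits$core_score >= 0.9 & hits$matrix_score >= 0.9, ]
  targeting <- tables$mirna_targets
  targeting <- targeting[targeting$target_id %in% target_pool, ]
  tcof_high <- tables$tcof_pairs[tables$tcof_pairs$confidence == "high", ]

  window_truth <- function(w) {
    pairs <- unique(passing[passing$window_nt == w, c("tf_id", "mirna_id")])
    tfs_w <- unique(pairs$tf_id)
    tc <- tcof_high[tcof_high$tf_id %in% tfs_w, ]
    tcofs_w <- unique(tc$tcof_id)
    proteins <- unique(c(target_pool, tfs_w, tcofs_w))
    pp <- tables$ppi_pairs
    pp <- pp[pp$protein_a %in% proteins & pp$protein_b %in% proteins, ]
    tce <- data.frame(protein_a = pmin(tc$tcof_id, tc$tf_id),
                      protein_b = pmax(tc$tcof_id, tc$tf_id),
                      stringsAsFactors = FALSE)
    ppi_all <- unique(rbind(pp, tce))
    list(
      n_mirnas = length(unique(targeting$mirna_id)),
      n_targets = length(unique(targeting$target_id)),
      n_tfs = length(tfs_w),
      n_tcofs = length(tcofs_w),
      n_edges_targeting = nrow(unique(targeting)),
      n_edges_regulation = nrow(pairs),
      n_edges_ppi = nrow(ppi_all),
      total_nodes = length(unique(targeting$mirna_id)) + length(proteins),
      total_edges = nrow(unique(targeting)) + nrow(pairs) + nrow(ppi_all))
  }

  list(
    seed = cfg$seed,
    table_rows = vapply(tables, nrow, 0L),
    planted_self_loops = psl,
    planted_feedback_loops = pfl,
    tfbs_pass_rate = if (nrow(hits)) mean(hits$core_score >= 0.9 &
                                            hits$matrix_score >= 0.9) else NA,
    windows = list(`1000` = window_truth(1000L),
                   `5000` = window_truth(5000L)))
}

#' Write generated tables and ledger to a directory
#'
#' Emits the five TSV tables plus `ledger.json`.
#'
#' @param generated result of [generate_tables()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_generated <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(generated$tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv(generated$tables[[nm]], p)
    paths[nm] <- p
  }
  lp <- file.path(dir, "ledger.json")
  jsonlite::write_json(generated$ledger, lp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths["ledger"] <- lp
  invisible(paths)
}

#' Build a network from generated tables at one promoter window
#'
#' Convenience wrapper: score- and window-filters the hit table and runs
#' [build_network()].
#'
#' @param generated result of [generate_tables()] (or any list with a
#'   `tables` element of the five canonical tables).
#' @param promoter_window 1000 or 5000.
#' @param min_core,min_matrix score thresholds passed to
#'   [filter_tfbs_hits()].
#' @return An `ocm_network`.
#' @export
build_from_tables <- function(generated, promoter_window,
                              min_core = 0.9, min_matrix = 0.9) {
  tb <- generated$tables
  build_network(
    mirna_targets = tb$mirna_targets,
    disease_genes = tb$disease_genes,
    tf_hits = filter_tfbs_hits(tb$tf_hits, min_core, min_matrix,
                               window_nt = promoter_window),
    tcof_pairs = tb$tcof_pairs,
    ppi_pairs = tb$ppi_pairs,
    promoter_window = promoter_window)
}
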