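# Synthetic snRNA-seq generator: a 15-donor cohort with binary amyloid/tau
# pathology and APOE/TREM2 genotypes, four nucleus populations (protoplasmic
# and fibrous astrocytes plus astrocyte-neuron and astrocyte-oligodendrocyte
# doublets), a latent reactivity axis in protoplasmic nuclei whose mean
# shifts with amyloid status, planted up/down gene programs over negative
# binomial counts, and a ground-truth channel for recovery tests.

default_marker_panels <- function(n = 10L) {
  panels <- list(
    protoplasmic = c("SLC1A2", "SLC1A3", "GLUL", "GJA1", "SLC4A4", "ATP1A2",
                     "MERTK", "FGFR3", "SOX9", "AQP4"),
    fibrous = c("GFAP", "CD44", "TNC", "ID3", "AQP1", "CRYAB", "S100B",
                "HOPX", "EMP1", "MT2A"),
    neuron = c("RBFOX3", "SYT1", "SNAP25", "GRIN1", "NEFL", "GAD1",
               "SLC17A7", "MAP2", "NRGN", "CELF4"),
    oligo = c("PLP1", "MBP", "MOG", "MOBP", "MAG", "CNP", "CLDN11",
              "OPALIN", "SOX10", "ST18")
  )
  lapply(panels, function(p) {
    if (n <= length(p)) p[seq_len(n)] else c(p, sprintf("%s_M%02d", p[1], seq_len(n - length(p))))
  })
}

#' Marker panels used by the synthetic generator and the annotator
#'
#' Named lists of population marker genes. Real gene symbols are attached
#' only as labels; in synthetic data these are ordinary simulated genes with
#' a population-specific high mean.
#'
#' @param n genes per panel.
#' @return named list with elements `protoplasmic`, `fibrous`, `neuron`,
#'   `oligo`.
#' @export
marker_panels <- function(n = 10L) default_marker_panels(n)

#' Simulation configuration
#'
#' Defines a synthetic cohort at desk scale: donor pathology/genotype mix,
#' population sizes in roughly the proportions reported for post-mortem
#' cortical astrocytes, planted up/down gene programs along a latent
#' reactivity axis, and negative binomial count noise.
#'
#' @param n_samples donors.
#' @param amyloid_positive,tau_positive number of pathology-positive donors.
#' @param apoe_freq,trem2_freq genotype probabilities (must sum to 1).
#' @param nuclei_per_type named counts for `protoplasmic`, `fibrous`,
#'   `doublet_neuron`, `doublet_oligo`.
#' @param n_genes total genes.
#' @param n_up,n_down planted top-program sizes (defaults 52 and 144).
#' @param slope_up,slope_down log-scale expression change per unit
#'   reactivity for planted genes.
#' @param n_weak,weak_slope_mean,weak_slope_sd size and slope distribution
#'   (normal) of the
#'   broad sub-program of reactivity-covarying genes. Real reactivity shifts
#'   a continuum of genes of which only the top pass screening thresholds;
#'   without this continuum the trajectory would carry far less variance
#'   than the data the analysis is designed for.
#' @param baseline_log_mean `c(mean, sd)` of null-gene log baseline rates.
#' @param planted_log_mean `c(mean, sd)` of planted-gene log baselines
#'   (dysregulated genes are modeled as well-expressed).
#' @param nb_dispersion `c(meanlog, sdlog)` of the log-normal per-gene NB
#'   dispersion.
#' @param depth_mean expected counts per nucleus.
#' @param amyloid_shift added to mean latent reactivity in amyloid-positive
#'   donors (default 0.118).
#' @param donor_sd SD of donor-level random intercepts on reactivity.
#' @param n_markers_per_panel,marker_boost marker-panel size and log-mean
#'   boost within the marker's own population.
#' @param astro_cross_boost log-mean boost of each astrocyte panel in the
#'   sister astrocyte subtype: protoplasmic and fibrous astrocytes are one
#'   cell type expressing both programs at graded levels, which keeps them
#'   adjacent (not islands) in expression space as in tissue.
#' @param malat1_log_mean log baseline of the very highly expressed nuclear
#'   transcript labeled MALAT1.
#' @param doublet_thin thin doublet counts back to singlet depth.
#' @param seed RNG seed.
#' @return `simulation_config` list, validated.
#' @export
simulation_config <- function(n_samples = 15L,
                              amyloid_positive = 8L,
                              tau_positive = 7L,
                              apoe_freq = c("E3/E3" = 0.6, "E3/E4" = 0.27, "E4/E4" = 0.13),
                              trem2_freq = c("WT" = 0.8, "R47H" = 0.2),
                              nuclei_per_type = c(protoplasmic = 1431L, fibrous = 837L,
                                                  doublet_neuron = 432L, doublet_oligo = 406L),
                              n_genes = 2000L,
                              n_up = 52L,
                              n_down = 144L,
                              slope_up = 0.3,
                              slope_down = -0.5,
                              n_weak = 600L,
                              weak_slope_mean = 0,
                              weak_slope_sd = 0.2,
                              baseline_log_mean = c(mean = 0, sd = 1),
                              planted_log_mean = c(mean = 1, sd = 0.5),
                              nb_dispersion = c(meanlog = log(0.1), sdlog = 0.4),
                              depth_mean = 12000,
                              amyloid_shift = 0.118,
                              donor_sd = 0.05,
                              n_markers_per_panel = 10L,
                              marker_boost = 2.5,
                              astro_cross_boost = 1.7,
                              malat1_log_mean = 4,
                              doublet_thin = TRUE,
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              amyloid_positive = as.integer(amyloid_positive),
              tau_positive = as.integer(tau_positive),
              apoe_freq = apoe_freq, trem2_freq = trem2_freq,
              nuclei_per_type = nuclei_per_type,
              n_genes = as.integer(n_genes),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              slope_up = slope_up, slope_down = slope_down,
              n_weak = as.integer(n_weak),
              weak_slope_mean = weak_slope_mean,
              weak_slope_sd = weak_slope_sd,
              baseline_log_mean = baseline_log_mean,
              planted_log_mean = planted_log_mean,
              nb_dispersion = nb_dispersion,
              depth_mean = depth_mean,
              amyloid_shift = amyloid_shift,
              donor_sd = donor_sd,
              n_markers_per_panel = as.integer(n_markers_per_panel),
              marker_boost = marker_boost,
              astro_cross_boost = astro_cross_boost,
              malat1_log_mean = malat1_log_mean,
              doublet_thin = isTRUE(doublet_thin),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  for (f in c("n_samples", "amyloid_positive", "tau_positive", "n_genes",
              "n_up", "n_down", "n_weak", "n_markers_per_panel")) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 0) {
      stop_field(f, "must be a single non-negative count")
    }
  }
  if (cfg$n_samples < 1) stop_field("n_samples", "need at least one donor")
  if (cfg$amyloid_positive > cfg$n_samples) {
    stop_field("amyloid_positive", "exceeds n_samples")
  }
  if (cfg$tau_positive > cfg$n_samples) stop_field("tau_positive", "exceeds n_samples")
  for (f in c("apoe_freq", "trem2_freq")) {
    p <- cfg[[f]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop_field(f, "probabilities must be non-negative and sum to 1")
    }
  }
  npt <- cfg$nuclei_per_type
  needed <- c("protoplasmic", "fibrous", "doublet_neuron", "doublet_oligo")
  if (!all(needed %in% names(npt))) {
    stop_field("nuclei_per_type", paste("must name", paste(needed, collapse = ", ")))
  }
  if (any(npt < 0)) stop_field("nuclei_per_type", "counts must be >= 0")
  n_special <- cfg$n_up + cfg$n_down + cfg$n_weak +
    4L * cfg$n_markers_per_panel + 1L
  if (n_special > cfg$n_genes) {
    stop_field("n_genes", sprintf(
      "too small: planted + weak + marker + MALAT1 genes need %d", n_special))
  }
  if (cfg$nb_dispersion[["sdlog"]] < 0) stop_field("nb_dispersion", "sdlog must be >= 0")
  if (cfg$depth_mean <= 0) stop_field("depth_mean", "must be positive")
  if (cfg$donor_sd < 0) stop_field("donor_sd", "must be >= 0")
  invisible(cfg)
}

# Gene table: names, roles, slopes, baselines, population boosts.
build_gene_table <- function(cfg) {
  panels <- default_marker_panels(cfg$n_markers_per_panel)
  up_named <- c("VIM", "CHI3L1")
  down_named <- c("NRXN1", "NRG3", "GPC5", "ERBB4", "NFIA")
  up <- c(head(up_named, cfg$n_up),
          sprintf("UPG%03d", seq_len(max(0, cfg$n_up - length(up_named)))))
  down <- c(head(down_named, cfg$n_down),
            sprintf("DNG%03d", seq_len(max(0, cfg$n_down - length(down_named)))))
  weak <- sprintf("WKG%03d", seq_len(cfg$n_weak))
  n_named <- length(up) + length(down) + length(weak) + sum(lengths(panels)) + 1L
  null_genes <- sprintf("G%05d", seq_len(cfg$n_genes - n_named))
  genes <- data.frame(
    gene = c(unlist(panels, use.names = FALSE), up, down, weak, "MALAT1", null_genes),
    direction = c(rep("marker", sum(lengths(panels))),
                  rep("up", length(up)), rep("down", length(down)),
                  rep("weak", length(weak)),
                  rep("null", 1L + length(null_genes))),
    stringsAsFactors = FALSE)
  genes$slope <- 0
  genes$slope[genes$direction == "up"] <- cfg$slope_up
  genes$slope[genes$direction == "down"] <- cfg$slope_down
  genes$slope[genes$direction == "weak"] <- rnorm(length(weak), cfg$weak_slope_mean,
                                                  cfg$weak_slope_sd)
  is_planted <- genes$direction %in% c("up", "down")
  genes$baseline <- rnorm(nrow(genes), cfg$baseline_log_mean[["mean"]],
                          cfg$baseline_log_mean[["sd"]])
  genes$baseline[is_planted] <- rnorm(sum(is_planted),
                                      cfg$planted_log_mean[["mean"]],
                                      cfg$planted_log_mean[["sd"]])
  genes$baseline[genes$direction == "marker"] <-
    rnorm(sum(genes$direction == "marker"), cfg$planted_log_mean[["mean"]],
          cfg$planted_log_mean[["sd"]])
  genes$baseline[genes$gene == "MALAT1"] <- cfg$malat1_log_mean
  genes$dispersion <- rlnorm(nrow(genes), cfg$nb_dispersion[["meanlog"]],
                             cfg$nb_dispersion[["sdlog"]])
  genes$panel <- NA_character_
  for (nm in names(panels)) genes$panel[genes$gene %in% panels[[nm]]] <- nm
  attr(genes, "panels") <- panels
  genes
}

shuffle <- function(x) x[sample.int(length(x))]

# Marker-panel log-mean boosts per population. The two astrocyte subtypes
# share each other's panels at a reduced level (they are the same cell type
# differing in degree), while neuron/oligodendrocyte programs are exclusive.
panel_boosts <- function(cfg) {
  full <- cfg$marker_boost
  cross <- cfg$astro_cross_boost
  list(protoplasmic = c(protoplasmic = full, fibrous = cross),
       fibrous = c(fibrous = full, protoplasmic = cross),
       neuron = c(neuron = full),
       oligo = c(oligo = full))
}

build_donor_table <- function(cfg) {
  ids <- sprintf("S%02d", seq_len(cfg$n_samples))
  data.frame(
    sample = ids,
    amyloid = shuffle(rep(c(1L, 0L), c(cfg$amyloid_positive,
                                       cfg$n_samples - cfg$amyloid_positive))),
    tau = shuffle(rep(c(1L, 0L), c(cfg$tau_positive,
                                   cfg$n_samples - cfg$tau_positive))),
    apoe = sample(names(cfg$apoe_freq), cfg$n_samples, TRUE, cfg$apoe_freq),
    trem2 = sample(names(cfg$trem2_freq), cfg$n_samples, TRUE, cfg$trem2_freq),
    age = round(runif(cfg$n_samples, 63, 95)),
    intercept = rnorm(cfg$n_samples, 0, cfg$donor_sd),
    stringsAsFactors = FALSE)
}

# Latent reactivity r in [0, 1]: Beta(2,2) interior mass plus donor random
# intercept plus the amyloid shift, clamped.
draw_r <- function(n, amyloid, intercept, shift) {
  pmin(1, pmax(0, rbeta(n, 2, 2) + shift * amyloid + intercept))
}

#' Draw per-nucleus latent reactivity for a cohort
#'
#' Generates the donor table and protoplasmic-nucleus reactivity values of a
#' simulated cohort without simulating counts; useful for studying the
#' pathology mixed model on its own.
#'
#' @param config a [simulation_config()].
#' @param nuclei_per_donor protoplasmic nuclei per donor (default spreads
#'   `nuclei_per_type["protoplasmic"]` evenly).
#' @return data.frame with nucleus_id, sample, amyloid, tau, apoe, trem2,
#'   age, and latent reactivity `r`.
#' @export
draw_reactivity <- function(config, nuclei_per_donor = NULL) {
  set.seed(config$seed)
  donors <- build_donor_table(config)
  npd <- nuclei_per_donor %||%
    ceiling(config$nuclei_per_type[["protoplasmic"]] / config$n_samples)
  idx <- rep(seq_len(nrow(donors)), each = npd)
  out <- donors[idx, c("sample", "amyloid", "tau", "apoe", "trem2", "age")]
  out$r <- draw_r(length(idx), donors$amyloid[idx], donors$intercept[idx],
                  config$amyloid_shift)
  out$nucleus_id <- sprintf("N%05d", seq_along(idx))
  rownames(out) <- NULL
  out[, c("nucleus_id", "sample", "amyloid", "tau", "apoe", "trem2", "age", "r")]
}

# Negative binomial counts for one population. `r` is the per-nucleus latent
# reactivity (NA for populations without a trajectory); `boost_panel` names
# the marker panel whose genes get the population's log-mean boost.
sim_population_counts <- function(genes, n, r, boost_panel, cfg) {
  if (n == 0) return(matrix(0L, 0, nrow(genes)))
  log_rate <- matrix(genes$baseline, n, nrow(genes), byrow = TRUE)
  for (nm in names(boost_panel)) {
    boosted <- !is.na(genes$panel) & genes$panel == nm
    log_rate[, boosted] <- log_rate[, boosted] + boost_panel[[nm]]
  }
  slope_cols <- genes$slope != 0
  if (any(slope_cols) && !all(is.na(r))) {
    log_rate[, slope_cols] <- log_rate[, slope_cols] +
      outer(r, genes$slope[slope_cols])
  }
  rate <- exp(log_rate)
  mu <- rate * (cfg$depth_mean / rowSums(rate))
  size <- matrix(1 / genes$dispersion, n, nrow(genes), byrow = TRUE)
  counts <- matrix(rnbinom(n * nrow(genes), mu = as.vector(mu),
                           size = as.vector(size)), n, nrow(genes))
  counts
}

#' Construct doublets by summing parent nuclei
#'
#' Each doublet's count vector is the sum of two sampled parent vectors (one
#' from each parent population), optionally thinned binomially back to a
#' target depth, emulating that a droplet yields one library's depth.
#'
#' @param counts nuclei x genes count matrix.
#' @param labels population label per nucleus (length `nrow(counts)`).
#' @param parents length-2 character vector of parent population labels.
#' @param n number of doublets.
#' @param target_depth depth to thin to; `NULL` disables thinning.
#' @return list with `counts` (n x genes), `parent_a`, `parent_b` (row
#'   indices into `counts`).
#' @export
make_doublets <- function(counts, labels, parents, n, target_depth = NULL) {
  stopifnot(length(parents) == 2)
  ia <- which(labels == parents[1])
  ib <- which(labels == parents[2])
  if (length(ia) == 0 || length(ib) == 0) {
    stop("both parent populations must be present", call. = FALSE)
  }
  if (n == 0) {
    return(list(counts = matrix(0L, 0, ncol(counts)),
                parent_a = integer(0), parent_b = integer(0)))
  }
  if (n > min(length(ia), length(ib))) {
    stop(sprintf("requested %d doublets but only %d parent pairs available",
                 n, min(length(ia), length(ib))), call. = FALSE)
  }
  pa <- ia[sample.int(length(ia), n)]
  pb <- ib[sample.int(length(ib), n)]
  dbl <- as.matrix(counts[pa, , drop = FALSE]) + as.matrix(counts[pb, , drop = FALSE])
  if (!is.null(target_depth)) {
    tot <- rowSums(dbl)
    for (i in seq_len(n)) {
      if (tot[i] > target_depth) {
        keep_p <- target_depth / tot[i]
        dbl[i, ] <- rbinom(ncol(dbl), size = dbl[i, ], prob = keep_p)
      }
    }
  }
  list(counts = dbl, parent_a = pa, parent_b = pb)
}

#' Simulate a synthetic snRNA-seq dataset
#'
#' Produces sparse counts, per-nucleus donor metadata and a ground-truth
#' channel (population labels, latent reactivity, doublet parents, per-gene
#' planted direction and slope). Protoplasmic nuclei carry the reactivity
#' trajectory; doublets are built from protoplasmic + neuron/oligodendrocyte
#' parent profiles and thinned to singlet depth.
#'
#' @param config a [simulation_config()].
#' @return `synthetic_dataset` list: `counts` (sparse nuclei x genes),
#'   `meta` (data.frame), `truth` (list with `nuclei` and `genes`
#'   data.frames), `config`.
#' @export
simulate_dataset <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  donors <- build_donor_table(config)
  genes <- build_gene_table(config)
  npt <- config$nuclei_per_type

  n_pro <- npt[["protoplasmic"]]
  n_fib <- npt[["fibrous"]]
  n_dn <- npt[["doublet_neuron"]]
  n_do <- npt[["doublet_oligo"]]

  assign_donors <- function(n) sample(seq_len(nrow(donors)), n, replace = TRUE)

  # protoplasmic singlets carry the trajectory
  pro_donor <- assign_donors(n_pro)
  pro_r <- draw_r(n_pro, donors$amyloid[pro_donor], donors$intercept[pro_donor],
                  config$amyloid_shift)
  boosts <- panel_boosts(config)
  pro_counts <- sim_population_counts(genes, n_pro, pro_r, boosts$protoplasmic, config)

  # fibrous singlets: no trajectory
  fib_donor <- assign_donors(n_fib)
  fib_counts <- sim_population_counts(genes, n_fib, NA, boosts$fibrous, config)

  # virtual parents for doublets (not part of the output dataset)
  make_dbl <- function(n_dbl, other_panel) {
    if (n_dbl == 0) {
      return(list(counts = matrix(0L, 0, nrow(genes)), donor = integer(0),
                  parent_a = character(0), parent_b = character(0)))
    }
    pd <- assign_donors(n_dbl)
    pr <- draw_r(n_dbl, donors$amyloid[pd], donors$intercept[pd],
                 config$amyloid_shift)
    astro_parent <- sim_population_counts(genes, n_dbl, pr, boosts$protoplasmic, config)
    other_parent <- sim_population_counts(genes, n_dbl, NA, boosts[[other_panel]], config)
    stacked <- rbind(astro_parent, other_parent)
    lab <- rep(c("astro", other_panel), each = n_dbl)
    dbl <- make_doublets(stacked, lab, c("astro", other_panel), n_dbl,
                         target_depth = if (config$doublet_thin) config$depth_mean else NULL)
    list(counts = dbl$counts, donor = pd,
         parent_a = sprintf("%s_parent_%04d", "astro", dbl$parent_a),
         parent_b = sprintf("%s_parent_%04d", other_panel, dbl$parent_b - n_dbl))
  }
  dn <- make_dbl(n_dn, "neuron")
  do_ <- make_dbl(n_do, "oligo")

  counts <- rbind(pro_counts, fib_counts, dn$counts, do_$counts)
  population <- rep(c("protoplasmic", "fibrous", "doublet_neuron", "doublet_oligo"),
                    c(n_pro, n_fib, n_dn, n_do))
  donor_idx <- c(pro_donor, fib_donor, dn$donor, do_$donor)
  n_total <- nrow(counts)
  ids <- sprintf("N%05d", seq_len(n_total))
  rownames(counts) <- ids
  colnames(counts) <- genes$gene

  meta <- cbind(data.frame(nucleus_id = ids, stringsAsFactors = FALSE),
                donors[donor_idx, c("sample", "amyloid", "tau", "apoe", "trem2", "age")])
  rownames(meta) <- NULL

  truth_nuclei <- data.frame(
    nucleus_id = ids,
    population = population,
    sample = donors$sample[donor_idx],
    r = c(pro_r, rep(NA_real_, n_fib),
          rep(NA_real_, n_dn), rep(NA_real_, n_do)),
    parent_a = c(rep(NA_character_, n_pro + n_fib), dn$parent_a, do_$parent_a),
    parent_b = c(rep(NA_character_, n_pro + n_fib), dn$parent_b, do_$parent_b),
    stringsAsFactors = FALSE)

  structure(list(
    counts = as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix"),
    meta = meta,
    truth = list(nuclei = truth_nuclei,
                 genes = genes[, c("gene", "direction", "slope", "baseline",
                                   "dispersion", "panel")]),
    config = config), class = "synthetic_dataset")
}

#' Microglia-like preset configuration
#'
#' A second-cell-type preset for re-running the identical screen on an
#' amyloid-responsive microglia-like population: a single trajectory-bearing
#' population whose planted program is predominantly upregulated (200 up at
#' +0.4 vs 30 down at -0.3), mirroring how disease-responsive microglia are
#' characterized mostly by induction rather than loss of expression.
#'
#' @param n_nuclei nuclei in the population.
#' @param seed RNG seed.
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
simulation_config_microglia <- function(n_nuclei = 1400L, seed = 1L, ...) {
  simulation_config(
    nuclei_per_type = c(protoplasmic = as.integer(n_nuclei), fibrous = 0L,
                        doublet_neuron = 0L, doublet_oligo = 0L),
    n_up = 200L, n_down = 30L, slope_up = 0.4, slope_down = -0.3,
    weak_slope_mean = 0.1, seed = seed, ...)
}

#' Planted signature from the ground truth
#'
#' @param truth the `truth` element of a `synthetic_dataset` (or the dataset
#'   itself).
#' @return list with `up` and `down` gene vectors.
#' @export
truth_signature <- function(truth) {
  if (inherits(truth, "synthetic_dataset")) truth <- truth$truth
  g <- truth$genes
  list(up = g$gene[g$direction == "up"], down = g$gene[g$direction == "down"])
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d nuclei x %d genes, %d donors\n",
              nrow(x$counts), ncol(x$counts), x$config$n_samples))
  print(table(x$truth$nuclei$population))
  invisible(x)
}
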