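# Synthetic study generator with planted cargo-bait ground truth.
#
# The generator emulates a BioID screen of nuclear transport receptors:
# a panel of BirA*-fusion cell lines plus control lines, measured in
# biological quadruplicate and technical duplicate; log2-scale protein
# intensities with planted cargo enrichment; intensity-dependent (MNAR)
# and random (MAR) dropout; control-enriched naturally biotinylated
# background proteins; and a planted-partition interaction network whose
# dense modules are protein complexes sharing one bait.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-study generator. The defaults
#' reproduce the full-screen design geometry (28 fusion samples in N/C
#' pairs plus 4 control lines, 4 biological x 2 technical replicates) with
#' log2 intensities centred at `mu` and realistic dropout.
#'
#' @param n_proteins number of protein groups.
#' @param n_ntrs number of bait fusion samples (cell lines); consecutive
#'   samples are paired into N- and C-terminal fusions of the same bait.
#' @param n_controls number of control cell lines.
#' @param n_bio,n_tech biological / technical replicates per cell line.
#' @param mu,tau mean and spread (SD) of per-protein baseline log2 abundance.
#' @param sigma_b,sigma_t biological / technical noise SD on the log2 scale
#'   (`sigma_t < sigma_b`).
#' @param delta planted cargo enrichment (log2 fold change) in the matching
#'   bait samples.
#' @param delta_ctrl enrichment of naturally biotinylated background
#'   proteins in control runs.
#' @param cargo_fraction,control_fraction fractions of proteins planted as
#'   cargo / control-enriched background (disjoint; must sum to < 1).
#' @param n_complexes,complex_size planted protein complexes: disjoint
#'   blocks of cargo proteins sharing one bait.
#' @param mnar_mid,mnar_steep logistic intensity-dependent dropout:
#'   P(missing) = plogis(-mnar_steep * (value - mnar_mid)). `mnar_steep = 0`
#'   with `mnar_mid = -Inf` disables it; see `dropout`.
#' @param mar_rate independent random dropout probability in [0, 1).
#' @param dropout set `FALSE` to disable all dropout (complete data).
#' @param p_in,p_out within-complex / background edge probabilities of the
#'   planted-partition interaction network (`p_in > p_out`).
#' @param weight_min minimum sampled edge weight (above the usual 0.7
#'   STRING-style cutoff).
#' @param site_proteins number of proteins carrying biotinylation sites.
#' @param sites_per_protein mean number of sites per site-bearing protein.
#' @param site_length assumed protein length for drawing site positions.
#' @param sigma_site site-level noise SD around the protein's run value.
#' @param site_on_cargo restrict site-bearing proteins to planted cargo
#'   (useful when studying abundance/site-count coupling).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 4000,
                       n_ntrs = 28, n_controls = 4,
                       n_bio = 4, n_tech = 2,
                       mu = 25, tau = 2,
                       sigma_b = 0.5, sigma_t = 0.2,
                       delta = 2, delta_ctrl = 2,
                       cargo_fraction = 0.3, control_fraction = 0.15,
                       n_complexes = 10, complex_size = 5,
                       mnar_mid = 20, mnar_steep = 1.5,
                       mar_rate = 0.02, dropout = TRUE,
                       p_in = 0.8, p_out = 0.002, weight_min = 0.71,
                       site_proteins = 100, sites_per_protein = 4,
                       site_length = 1000, sigma_site = 0.3,
                       site_on_cargo = FALSE) {
  cfg <- as.list(environment())
  if (sigma_b <= 0 || sigma_t <= 0 || tau <= 0) {
    stop_config("noise parameters tau, sigma_b, sigma_t must be > 0")
  }
  if (sigma_t >= sigma_b) {
    stop_config("technical noise sigma_t must be smaller than biological sigma_b")
  }
  if (mar_rate < 0 || mar_rate >= 1) stop_config("mar_rate must be in [0, 1)")
  if (cargo_fraction + control_fraction > 1) {
    stop_config("cargo_fraction + control_fraction exceed 1")
  }
  if (n_complexes * complex_size > cargo_fraction * n_proteins) {
    stop_config("planted complexes require more cargo proteins than available")
  }
  structure(cfg, class = "sim_config")
}

sample_names <- function(config) {
  n <- config$n_ntrs
  bait <- paste0("NTR", sprintf("%02d", ceiling(seq_len(n) / 2)))
  term <- rep(c("N", "C"), length.out = n)
  list(line = paste0(bait, "_", term), bait = bait, terminus = term)
}

#' Generate the study design
#'
#' `n_ntrs` fusion cell lines (paired N/C termini of `ceiling(n_ntrs/2)`
#' baits) plus `n_controls` control lines, each measured `n_bio` x `n_tech`
#' times. With the default full-screen geometry this yields 256 runs and
#' 16 control experiments.
#'
#' @param config a [sim_config()].
#' @return A validated design tibble (see [read_design()]).
#' @export
simulate_design <- function(config = sim_config()) {
  sn <- sample_names(config)
  lines <- tibble(
    cell_line = c(sn$line, paste0("CTRL", sprintf("%02d", seq_len(config$n_controls)))),
    bait = c(sn$bait, rep("control", config$n_controls)),
    terminus = c(sn$terminus, rep("none", config$n_controls)),
    is_control = c(rep(FALSE, config$n_ntrs), rep(TRUE, config$n_controls))
  )
  design <- tidyr::expand_grid(lines,
                               bio_rep = seq_len(config$n_bio),
                               tech_rep = seq_len(config$n_tech))
  design$run_id <- sprintf("%s_b%d_t%d", design$cell_line,
                           design$bio_rep, design$tech_rep)
  validate_design(design[DESIGN_COLS])
}

#' Plant the ground truth
#'
#' Draws disjoint cargo and control-enriched protein sets, assigns each
#' cargo protein one bait, and carves the first cargo proteins into
#' disjoint complexes whose members share their complex's bait.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A `ground_truth` list: `cargo` tibble (`protein`, `bait`,
#'   `complex`), `control_enriched` character vector, `complexes` named
#'   list of protein sets, `proteins` (all ids), `baits` (all bait ids).
#' @export
simulate_truth <- function(config = sim_config(), seed = 1) {
  set.seed(substream_seed(seed, "truth"))
  prot <- sprintf("P%05d", seq_len(config$n_proteins))
  n_cargo <- round(config$cargo_fraction * config$n_proteins)
  n_ctrl <- round(config$control_fraction * config$n_proteins)
  picked <- sample(prot, n_cargo + n_ctrl)
  cargo_ids <- picked[seq_len(n_cargo)]
  control_enriched <- picked[n_cargo + seq_len(n_ctrl)]

  baits <- unique(sample_names(config)$bait)
  cargo <- tibble(protein = cargo_ids,
                  bait = sample(baits, n_cargo, replace = TRUE),
                  complex = NA_character_)

  complexes <- list()
  if (config$n_complexes > 0) {
    for (i in seq_len(config$n_complexes)) {
      members <- cargo_ids[(i - 1) * config$complex_size + seq_len(config$complex_size)]
      cx <- sprintf("complex%02d", i)
      cx_bait <- sample(baits, 1)
      cargo$bait[match(members, cargo$protein)] <- cx_bait
      cargo$complex[match(members, cargo$protein)] <- cx
      complexes[[cx]] <- members
    }
  }
  structure(list(cargo = cargo, control_enriched = control_enriched,
                 complexes = complexes, proteins = prot, baits = baits),
            class = "ground_truth")
}

#' Simulate the proteins-by-runs intensity matrix
#'
#' Log2 value of protein g in run r is
#' `a_g + delta * [g cargo of bait(r)] + delta_ctrl * [g control-enriched
#' and r control] + b_(g, line, bio) + t_(g, r)` with
#' `a_g ~ N(mu, tau^2)`, biological noise `b ~ N(0, sigma_b^2)` shared by
#' technical replicates, and technical noise `t ~ N(0, sigma_t^2)`.
#' Dropout is applied afterwards: a cell goes missing with probability
#' `plogis(-mnar_steep * (value - mnar_mid))` (intensity-dependent, MNAR)
#' or independently with probability `mar_rate` (MAR).
#'
#' @param design design tibble from [simulate_design()].
#' @param truth ground truth from [simulate_truth()].
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give bit-identical matrices.
#' @return A log2-scale [intensity_matrix()].
#' @export
simulate_intensities <- function(design, truth, config = sim_config(), seed = 1) {
  set.seed(substream_seed(seed, "intensities"))
  prot <- truth$proteins
  np <- length(prot)
  nr <- nrow(design)

  a <- rnorm(np, config$mu, config$tau)

  cargo_effect <- matrix(0, np, nr)
  cargo_idx <- match(truth$cargo$protein, prot)
  bait_of_run <- design$bait
  for (i in seq_along(cargo_idx)) {
    cargo_effect[cargo_idx[i], bait_of_run == truth$cargo$bait[i]] <- config$delta
  }
  ctrl_idx <- match(truth$control_enriched, prot)
  cargo_effect[ctrl_idx, design$is_control] <-
    cargo_effect[ctrl_idx, design$is_control] + config$delta_ctrl

  # biological noise shared across technical replicates of one (line, bio)
  bio_key <- paste(design$cell_line, design$bio_rep)
  bio_levels <- unique(bio_key)
  b <- matrix(rnorm(np * length(bio_levels), 0, config$sigma_b),
              np, length(bio_levels))
  tech <- matrix(rnorm(np * nr, 0, config$sigma_t), np, nr)

  vals <- a + cargo_effect + b[, match(bio_key, bio_levels), drop = FALSE] + tech

  if (isTRUE(config$dropout)) {
    p_mnar <- stats::plogis(-config$mnar_steep * (vals - config$mnar_mid))
    miss <- matrix(runif(np * nr) < p_mnar, np, nr) |
      matrix(runif(np * nr) < config$mar_rate, np, nr)
    vals[miss] <- NA_real_
  }
  colnames(vals) <- design$run_id
  proteins <- tibble(group_id = prot, gene_name = prot,
                     unique_peptides = 2L + rpois(np, 6),
                     is_reverse = FALSE, is_contaminant = FALSE)
  intensity_matrix(vals, proteins, scale = "log2")
}

#' Simulate the interaction network
#'
#' Planted-partition graph over all proteins: node pairs inside one planted
#' complex are connected with probability `p_in`, all other pairs with
#' probability `p_out`; realized edges get weights uniform on
#' `[weight_min, 1]`, i.e. above the usual combined-score cutoff.
#'
#' @inheritParams simulate_intensities
#' @return A `ppi_network` (see [read_network()]).
#' @export
simulate_network <- function(truth, config = sim_config(), seed = 1) {
  if (config$p_in <= config$p_out) stop_config("p_in must exceed p_out")
  set.seed(substream_seed(seed, "network"))
  prot <- truth$proteins
  np <- length(prot)

  edges <- list()
  for (members in truth$complexes) {
    idx <- which(stats::runif(choose(length(members), 2)) < config$p_in)
    if (length(idx)) {
      pairs <- utils::combn(members, 2)
      edges[[length(edges) + 1]] <- tibble(from = pairs[1, idx], to = pairs[2, idx])
    }
  }
  # sparse background edges: draw the count, then sample distinct pairs
  n_pairs <- choose(np, 2)
  n_bg <- rbinom(1, min(n_pairs, .Machine$integer.max), config$p_out)
  if (n_bg > 0) {
    i <- sample.int(np, n_bg, replace = TRUE)
    j <- sample.int(np, n_bg, replace = TRUE)
    ok <- i != j
    edges[[length(edges) + 1]] <- tibble(from = prot[pmin(i[ok], j[ok])],
                                         to = prot[pmax(i[ok], j[ok])])
  }
  edges <- dplyr::distinct(dplyr::bind_rows(edges))
  edges$weight <- runif(nrow(edges), config$weight_min, 1)
  as_ppi_network(edges, threshold = config$weight_min - 0.001, extra_nodes = prot)
}

#' Simulate a biotinylation-site table
#'
#' A subset of proteins carries 1 + Poisson sites at random residue
#' positions; a site's log2 intensity in a run tracks the protein's
#' (noise-free) value in that run plus a site-specific offset and noise,
#' and is subject to the same dropout model as the protein matrix.
#'
#' @inheritParams simulate_intensities
#' @return A site-level [intensity_matrix()] whose `sites` field holds
#'   (`protein`, `position`); attribute `site_proteins` lists the chosen
#'   proteins.
#' @export
simulate_sites <- function(design, truth, config = sim_config(), seed = 1) {
  set.seed(substream_seed(seed, "sites"))
  pool <- if (isTRUE(config$site_on_cargo)) truth$cargo$protein else truth$proteins
  chosen <- sample(pool, min(config$site_proteins, length(pool)))
  n_sites <- 1L + rpois(length(chosen), config$sites_per_protein - 1)
  sites <- tibble(
    protein = rep(chosen, n_sites),
    position = unlist(lapply(n_sites, function(k) {
      sort(sample.int(config$site_length, k))
    }))
  )
  sites <- dplyr::distinct(sites)

  # protein-level expected value per run (baseline + planted effects)
  a <- rnorm(length(truth$proteins), config$mu, config$tau)
  names(a) <- truth$proteins
  nr <- nrow(design)
  base <- matrix(rep(a[sites$protein], nr), nrow(sites), nr)
  cargo_idx <- match(sites$protein, truth$cargo$protein)
  has_bait <- !is.na(cargo_idx)
  for (k in which(has_bait)) {
    base[k, design$bait == truth$cargo$bait[cargo_idx[k]]] <-
      base[k, design$bait == truth$cargo$bait[cargo_idx[k]]] + config$delta
  }
  offset <- rnorm(nrow(sites), 0, 1)
  vals <- base + offset + matrix(rnorm(nrow(sites) * nr, 0, config$sigma_site),
                                 nrow(sites), nr)
  if (isTRUE(config$dropout)) {
    p_mnar <- stats::plogis(-config$mnar_steep * (vals - config$mnar_mid))
    miss <- matrix(runif(length(vals)) < p_mnar, nrow(sites), nr) |
      matrix(runif(length(vals)) < config$mar_rate, nrow(sites), nr)
    vals[miss] <- NA_real_
  }
  colnames(vals) <- design$run_id
  m <- intensity_matrix(vals,
                        tibble(group_id = paste0(sites$protein, "@", sites$position)),
                        scale = "log2", sites = sites)
  attr(m, "site_proteins") <- chosen
  m
}
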