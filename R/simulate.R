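# Coalescent simulator for constant-size and two-epoch sudden-expansion
# demographies.
#
# Time is measured in mutational units: mutations fall on each lineage as a
# Poisson process of rate 1/2 per unit, so a pair whose lineages coalesce
# at depth s carries Poisson(s) expected differences, and at equilibrium
# E[pairwise differences] = theta. The coalescence rate for i active
# lineages is i(i-1)/(2 theta(t)), with theta(t) = theta1 for t < tau
# (after the expansion, looking back) and theta0 for t >= tau (before it).

#' Simulation configuration
#'
#' @param n number of sampled sequences (`>= 2`).
#' @param theta0 scaled size before the expansion (backwards of `tau`).
#' @param theta1 scaled size after the expansion (the present epoch).
#' @param theta convenience: sets both `theta0` and `theta1` (constant
#'   size); ignored when the epoch thetas are given explicitly.
#' @param tau expansion age in mutational time units; `0` means constant
#'   size.
#' @param L alignment length in sites (defaults to the mitogenome analysis
#'   length 16038).
#' @param seed optional integer seed recorded in the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n, theta0 = theta, theta1 = theta, theta = NULL,
                       tau = 0, L = 16038L, seed = NULL) {
  if (is.null(theta0) || is.null(theta1))
    stop("sim_config: supply theta, or both theta0 and theta1")
  stopifnot(n >= 2L, theta0 > 0, theta1 > 0, tau >= 0, L >= 1L)
  structure(list(n = as.integer(n), theta0 = theta0, theta1 = theta1,
                 tau = tau, L = as.integer(L), seed = seed),
            class = "sim_config")
}

# Simulate a genealogy: returns node times (2n-1 nodes, leaves 1..n at
# time 0) and a parent vector. Merge pairs chosen uniformly.
.sim_tree <- function(n, theta0, theta1, tau) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    i <- length(active)
    rate1 <- i * (i - 1) / (2 * theta1)
    rate0 <- i * (i - 1) / (2 * theta0)
    if (t < tau) {
      w <- stats::rexp(1L, rate1)
      t <- if (t + w < tau) t + w else tau + stats::rexp(1L, rate0)
    } else {
      t <- t + stats::rexp(1L, rate0)
    }
    pick <- sample.int(i, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    parent[a] <- nxt; parent[b] <- nxt
    time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, time = time, n = n)
}

# Poisson mutation counts per branch (rate 1/2 per unit length).
.sim_branch_mutations <- function(tree) {
  n_nodes <- 2L * tree$n - 1L
  len <- numeric(n_nodes)
  has_parent <- tree$parent != 0L
  len[has_parent] <- tree$time[tree$parent[has_parent]] - tree$time[has_parent]
  mut <- integer(n_nodes)
  mut[has_parent] <- stats::rpois(sum(has_parent), len[has_parent] / 2)
  mut
}

# Leaves descending from every node.
.descendant_leaves <- function(tree) {
  n <- tree$n
  n_nodes <- 2L * n - 1L
  desc <- vector("list", n_nodes)
  for (v in seq_len(n)) desc[[v]] <- v
  for (v in (n + 1L):n_nodes) { # children have smaller index than parent
    kids <- which(tree$parent == v)
    desc[[v]] <- c(desc[[kids[1L]]], desc[[kids[2L]]])
  }
  desc
}

# Pairwise differences implied by per-branch mutation counts (infinite
# sites: every mutation separates the clade under its branch from the rest).
.pair_diffs_from_tree <- function(tree, mut) {
  n <- tree$n
  D <- matrix(0L, n, n)
  desc <- .descendant_leaves(tree)
  for (v in which(mut > 0L)) {
    inside <- desc[[v]]
    D[inside, -inside] <- D[inside, -inside] + mut[v]
    D[-inside, inside] <- D[-inside, inside] + mut[v]
  }
  D
}

#' Simulate genealogy-level summary statistics
#'
#' Draws one coalescent genealogy with mutations under the configured
#' demography and returns the summaries every downstream test statistic
#' needs, without materialising sequences: the pairwise difference matrix,
#' `S` (total mutations; infinite sites), `K` (mean pairwise difference)
#' and `H` (number of distinct haplotypes).
#'
#' @param cfg a [sim_config()]. Uses the current RNG state (set a seed
#'   externally, or via `cfg$seed`).
#' @return list with `D` (n x n), `S`, `K`, `H`.
#' @export
simulate_summary <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tree <- .sim_tree(cfg$n, cfg$theta0, cfg$theta1, cfg$tau)
  mut <- .sim_branch_mutations(tree)
  D <- .pair_diffs_from_tree(tree, mut)
  # identical haplotypes <=> zero path mutations <=> identical D rows
  H <- nrow(unique(D))
  list(D = D, S = sum(mut), K = mean(D[upper.tri(D)]), H = H)
}

#' Simulate an alignment under a coalescent demography
#'
#' Generates one genealogy, drops mutations on branches, places each
#' mutation at a distinct uniformly chosen site of an all-`A` ancestor
#' (infinite-sites onto `L` positions; site collisions avoided by drawing
#' without replacement) with a uniformly chosen alternative base, and
#' propagates the derived states to the sampled leaves.
#'
#' @param cfg a [sim_config()].
#' @return list with `alignment` (a `dna_alignment`, ids `s1..sn`) and
#'   `truth` (config echo, coalescence times in mutational units, mutation
#'   count, per-branch mutation bookkeeping).
#' @export
simulate_alignment <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tree <- .sim_tree(cfg$n, cfg$theta0, cfg$theta1, cfg$tau)
  mut <- .sim_branch_mutations(tree)
  S <- sum(mut)
  if (S > cfg$L)
    stop("saturation error: ", S, " mutations exceed L = ", cfg$L, " sites")
  if (S > cfg$L / 10)
    warning("mutation count (", S, ") is not small relative to L = ", cfg$L,
            "; infinite-sites approximation is strained")
  mat <- matrix("A", nrow = cfg$n, ncol = cfg$L)
  sites <- if (S > 0L) sample.int(cfg$L, S) else integer(0)
  desc <- .descendant_leaves(tree)
  alt_pool <- list(A = c("C", "G", "T"))
  s_idx <- 0L
  site_of <- integer(0)
  branch_of <- integer(0)
  for (v in which(mut > 0L)) {
    for (m in seq_len(mut[v])) {
      s_idx <- s_idx + 1L
      site <- sites[s_idx]
      alt <- sample(alt_pool$A, 1L)
      mat[desc[[v]], site] <- alt
      site_of <- c(site_of, site)
      branch_of <- c(branch_of, v)
    }
  }
  ids <- paste0("s", seq_len(cfg$n))
  rownames(mat) <- ids
  aln <- structure(list(ids = ids, mat = mat), class = "dna_alignment")
  truth <- list(config = unclass(cfg),
                coal_times = sort(tree$time[(cfg$n + 1L):(2L * cfg$n - 1L)]),
                n_mutations = S,
                mutation_sites = site_of,
                mutation_branches = branch_of)
  list(alignment = aln, truth = truth)
}

#' Write a panel of simulated fixture scenarios
#'
#' Each scenario becomes a directory with `alignment.fasta`,
#' `metadata.tsv` (all samples labelled with the scenario name) and
#' `truth.json`. The default panel mimics the expansion-flagged study
#' groups: an n=13 strongly star-like expansion, an n=24 expansion and an
#' n=11 weak-signal group, with the printed tau values as the stated truth
#' and Arlequin-style near-zero theta0 / effectively infinite theta1 for
#' the strong expansions.
#'
#' @param dir output directory (created if needed).
#' @param scenarios named list of [sim_config()] objects.
#' @param seed integer seed; scenario i uses `seed + i`.
#' @return invisibly, the scenario directories written.
#' @export
make_fixture_panel <- function(dir,
                               scenarios = default_fixture_scenarios(),
                               seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (i in seq_along(scenarios)) {
    nm <- names(scenarios)[i]
    cfg <- scenarios[[i]]
    cfg$seed <- as.integer(seed + i)
    sdir <- file.path(dir, nm)
    dir.create(sdir, showWarnings = FALSE)
    sim <- simulate_alignment(cfg)
    write_fasta_alignment(sim$alignment, file.path(sdir, "alignment.fasta"))
    utils::write.table(
      data.frame(sample_id = sim$alignment$ids, group = nm,
                 locality = "synthetic"),
      file.path(sdir, "metadata.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(sim$truth, file.path(sdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, sdir)
  }
  invisible(written)
}

#' Default fixture scenarios
#'
#' Group sizes follow the printed expansion rows (n = 13, 24, 11); tau
#' values follow the printed point estimates; the strong expansions use a
#' small theta0 and an effectively infinite theta1, the weak-signal
#' scenario a mild size contrast.
#'
#' @return named list of `sim_config`s.
#' @export
default_fixture_scenarios <- function() {
  list(
    "M1a7-3J-like" = sim_config(n = 13, theta0 = 0.5, theta1 = 1e5, tau = 9.523),
    "C1a1-like"    = sim_config(n = 24, theta0 = 0.5, theta1 = 1e5, tau = 14.219),
    "C1a1-5-like"  = sim_config(n = 11, theta0 = 2,   theta1 = 30,  tau = 11.586)
  )
}
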