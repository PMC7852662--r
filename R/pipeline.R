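# End-to-end orchestration: load -> clean -> per-group diversity,
# neutrality, mismatch fit + bootstrap, expansion-time tables -> MJ
# networks -> reports. Deterministic given the config seed; per-group
# failures are logged and skipped, never silently dropped.

#' Analysis configuration
#'
#' @param alignment path to the FASTA alignment.
#' @param metadata path to the metadata TSV (`sample_id`, `group`).
#' @param outdir output directory.
#' @param missing_policy missing-data policy for difference counting.
#' @param clean_policy column-cleaning policy (see [clean_columns()]).
#' @param reps bootstrap / null-simulation replicates (a warning is issued
#'   below 100; publishable runs use 1000).
#' @param seed integer base seed; per-group seeds are derived from it.
#' @param rates reporting rates for the expansion-time table.
#' @param k sites override for time conversion; default = cleaned
#'   alignment length.
#' @param epsilon MJ network relaxation parameter.
#' @param network_groups group labels to build networks for (`NULL` = all
#'   eligible).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(alignment, metadata, outdir = "mitodemog-out",
                            missing_policy = "pairwise-deletion",
                            clean_policy = "drop-gap-columns",
                            reps = 1000L, seed = 1L,
                            rates = c(0.9e-7, 1.1e-7, 2.0e-7, 4.0e-7),
                            k = NULL, epsilon = 0L, network_groups = NULL) {
  if (!file.exists(alignment)) stop("input error: alignment not found: ", alignment)
  if (!file.exists(metadata)) stop("input error: metadata not found: ", metadata)
  if (reps < 100L)
    warning("reps < 100: p-values will be coarse; use >= 1000 for publishable runs")
  structure(list(alignment = alignment, metadata = metadata, outdir = outdir,
                 missing_policy = missing_policy, clean_policy = clean_policy,
                 reps = as.integer(reps), seed = as.integer(seed),
                 rates = rates, k = k, epsilon = as.integer(epsilon),
                 network_groups = network_groups),
            class = "analysis_config")
}

#' Read an analysis config from a JSON document
#' @param path JSON file whose keys are [analysis_config()] arguments.
#' @param ... overrides applied on top of the file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path, ...) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  doc[names(over)] <- over
  do.call(analysis_config, doc)
}

# deterministic per-group seed below 2^31
.derive_seed <- function(seed, i) (as.integer(seed) %% 1000000L) * 1009L + 97L * i

#' Run the full demographic-inference pipeline
#'
#' Stages: load alignment and metadata, clean columns, then per group with
#' `n >= 2`: diversity summary; for groups meeting the preconditions
#' (`n >= 4`, `S >= 1`, at least two occupied mismatch classes):
#' neutrality tests, sudden-expansion fit with parametric bootstrap, and
#' the expansion-time table at each configured rate. MJ networks are built
#' for the requested groups with `H >= 2`. Reports (diversity TSV,
#' demography TSV with one time column per rate, network GraphML/NEXUS/TSV
#' files, JSON run manifest, run log) are written to `cfg$outdir`. Every
#' skipped group appears in the log with its reason. Deterministic given
#' `cfg$seed`; output files carry no timestamps so a re-run with the same
#' config is byte-identical.
#'
#' @param cfg an [analysis_config()].
#' @param quiet suppress progress messages.
#' @return object of class `report_bundle`: `diversity` (data.frame),
#'   `demography` (data.frame), `networks` (named list of
#'   `haplotype_network`s), `skipped` (named reasons), `files`.
#' @export
run_analysis <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "analysis_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  note("mitodemog run: seed=%d reps=%d policy=%s", cfg$seed, cfg$reps,
       cfg$missing_policy)
  aln <- read_fasta_alignment(cfg$alignment)
  g <- read_group_table(cfg$metadata)
  aln <- clean_columns(aln, cfg$clean_policy)
  k <- if (is.null(cfg$k)) n_sites(aln) else cfg$k
  note("alignment: n=%d, L=%d after cleaning; k=%g for time conversion",
       n_seq(aln), n_sites(aln), k)
  labs <- unique(g$group[g$sample_id %in% aln$ids])
  div_rows <- list(); dem_rows <- list(); networks <- list()
  skipped <- character(0)
  rate_tags <- sprintf("T_rate_%.1fe-7", cfg$rates * 1e7)
  for (i in seq_along(labs)) {
    lab <- labs[[i]]
    sub <- subset_by_group(aln, g, lab)
    if (n_seq(sub) < 2L) {
      skipped[lab] <- "insufficient-sample"
      note("group '%s' skipped: insufficient-sample (n=%d)", lab, n_seq(sub))
      next
    }
    div <- summarize_diversity(sub, cfg$missing_policy)
    div_rows[[lab]] <- cbind(data.frame(group = lab), as.data.frame(div))
    gseed <- .derive_seed(cfg$seed, i)
    dem <- tryCatch({
      if (n_seq(sub) < 4L) stop("insufficient-sample for neutrality (n < 4)")
      nt <- neutrality_test(sub, reps = cfg$reps, seed = gseed,
                            missing_policy = cfg$missing_policy)
      pd <- pairwise_differences(sub, cfg$missing_policy)
      mm <- observed_mismatch(pd)
      fit <- fit_sudden_expansion(mm)
      fit <- bootstrap_expansion_test(sub, fit, reps = cfg$reps,
                                      seed = gseed + 1L)
      tt <- expansion_time_table(fit, rates = cfg$rates, k = k)
      row <- data.frame(group = lab, n = n_seq(sub),
                        Pi_percent = div$Pi_percent,
                        D = nt$D, p_D = nt$p_D, Fs = nt$Fs, p_Fs = nt$p_Fs,
                        tau = fit$tau, tau_CI_low = fit$tau_CI[1],
                        tau_CI_high = fit$tau_CI[2],
                        SSD = fit$SSD, p_SSD = fit$p_SSD,
                        r = fit$r, p_r = fit$p_r,
                        expansion_rejected = fit$p_SSD < 0.05,
                        seed = gseed)
      for (ri in seq_along(cfg$rates)) row[[rate_tags[ri]]] <- tt$T_years[ri]
      # internal consistency: printed times must satisfy T = tau/(2 mu k)
      stopifnot(all(row[rate_tags] ==
                      round(fit$tau / (2 * cfg$rates * k))))
      row
    }, error = function(e) {
      skipped[lab] <<- conditionMessage(e)
      note("group '%s' demography skipped: %s", lab, conditionMessage(e))
      NULL
    })
    if (!is.null(dem)) dem_rows[[lab]] <- dem
    want_net <- is.null(cfg$network_groups) || lab %in% cfg$network_groups
    if (want_net) {
      hs <- collapse_haplotypes(sub)
      if (hs$H >= 2L) {
        net <- build_mj_network(hs, epsilon = cfg$epsilon, groups = g)
        networks[[lab]] <- net
        base <- file.path(cfg$outdir, paste0("network-", gsub("[^A-Za-z0-9._-]", "_", lab)))
        write_network_graphml(net, paste0(base, ".graphml"))
        write_network_nexus(net, paste0(base, ".nex"))
        write_network_edges(net, paste0(base, "-edges.tsv"))
        s <- network_summary(net)
        note("group '%s' network: %d nodes, %d edges, star-likeness %.3f",
             lab, s$n_nodes, s$n_edges, s$star_likeness)
      } else {
        note("group '%s' network skipped: single haplotype", lab)
      }
    }
  }
  if (!length(div_rows)) {
    writeLines(log_lines, file.path(cfg$outdir, "run.log"))
    stop("all groups failed; see run log")
  }
  diversity <- do.call(rbind, div_rows); rownames(diversity) <- NULL
  demography <- if (length(dem_rows)) {
    x <- do.call(rbind, dem_rows); rownames(x) <- NULL; x
  } else NULL
  files <- list(diversity = file.path(cfg$outdir, "diversity.tsv"),
                demography = file.path(cfg$outdir, "demography.tsv"),
                manifest = file.path(cfg$outdir, "run_manifest.json"),
                log = file.path(cfg$outdir, "run.log"))
  write_diversity_table(diversity, files$diversity)
  if (!is.null(demography))
    utils::write.table(demography, files$demography, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  manifest <- list(package = "mitodemog",
                   version = as.character(utils::packageVersion("mitodemog")),
                   seed = cfg$seed, reps = cfg$reps,
                   missing_policy = cfg$missing_policy,
                   clean_policy = cfg$clean_policy, k = k,
                   rates = cfg$rates, epsilon = cfg$epsilon,
                   alignment = cfg$alignment, metadata = cfg$metadata,
                   groups_analysed = names(div_rows),
                   groups_skipped = as.list(skipped))
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, files$log)
  structure(list(diversity = diversity, demography = demography,
                 networks = networks, skipped = skipped, files = files,
                 config = cfg),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("report_bundle: %d diversity rows, %d demography rows, %d networks\n",
              nrow(x$diversity),
              if (is.null(x$demography)) 0L else nrow(x$demography),
              length(x$networks)))
  if (length(x$skipped))
    cat("  skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  invisible(x)
}
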