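# Configuration-driven orchestration: simulate/load -> H-bonds -> binding
# states -> geometry -> energetics / collective dynamics -> network ->
# report. Every "bound frames only" analysis downstream is fed the frame
# masks produced by the binding classifier, and all tabular outputs are
# TSV so a re-run with the same configuration and seed is byte-identical.

.RUN_CONFIG_KEYS <- c(
  "conditions", "dt", "equil_ns", "persistence", "allow_rebinding",
  "network_threshold", "sources", "sinks", "n_paths", "latch_pairs",
  "termination_pairs", "termination_threshold", "energy", "pca_exclude",
  "core_clusters", "core_residues", "seed", "stages"
)

#' Validate and normalise a run configuration
#'
#' A configuration is a named list (or YAML file) with keys:
#' `conditions` (named list; each entry either a [synthetic_spec()] under
#' `$spec`, or `$structure`/`$trajectories`/`$dt` paths), `equil_ns`
#' (initial ns excluded from statistics, default 50), `persistence` (ns,
#' default 5), `allow_rebinding`, `network_threshold` (default 0.7),
#' `sources`/`sinks` (network node names), `n_paths` (default 500),
#' `latch_pairs`, `termination_pairs`/`termination_threshold`, `energy`
#' (list with `groupA`/`groupB` selections), `pca_exclude` (residue ids),
#' `core_clusters` (default 5), `seed`, `stages` (character subset to run).
#' Unknown keys are rejected before any computation.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), .RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$conditions) || !length(config$conditions)) {
    stop("configuration must declare at least one condition")
  }
  defaults <- list(equil_ns = 50, persistence = 5, allow_rebinding = FALSE,
                   network_threshold = 0.7, n_paths = 500,
                   termination_threshold = 80, core_clusters = 5,
                   stages = c("simulate", "hbonds", "bind", "geometry",
                              "energy", "pca", "network", "report"))
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  config
}

#' Run the full analysis pipeline
#'
#' @param config See [validate_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the configuration seed; all
#'   stochastic stages derive their streams from it.
#' @return A `run_report`: per-stage status, parameter echo, output-file
#'   manifest with MD5 hashes, and the in-memory `results` of each stage.
#' @export
run_pipeline <- function(config, out_dir = tempfile("hingelatch-run-"),
                         seed = NULL) {
  config <- validate_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  results <- list()
  log_stage <- function(name, detail) {
    stages <<- c(stages, name)
    message(sprintf("[%s] %s", name, detail))
  }
  fail <- function(stage, e) {
    stop("pipeline aborted in stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }

  # -- simulate / load ---------------------------------------------------
  ensembles <- list(); truths <- list()
  tryCatch({
    ci <- 0L
    for (cond in names(config$conditions)) {
      ci <- ci + 1L
      cc <- config$conditions[[cond]]
      if (!is.null(cc$spec)) {
        spec <- cc$spec
        if (!is.null(config$seed)) {
          spec$seed <- as.integer(config$seed) + (ci - 1L) * 1009L
        }
        sim <- simulate_ensemble(spec, condition = cond)
        ensembles[[cond]] <- sim$ensemble
        truths[[cond]] <- sim$truth
      } else {
        st <- read_structure(cc$structure, domain_map = cc$domain_map,
                             param_table = if (!is.null(cc$params))
                               read_param_table(cc$params) else NULL)
        trajs <- lapply(seq_along(cc$trajectories), function(i) {
          read_trajectory(cc$trajectories[[i]], st$top, dt = cc$dt,
                          replica_id = paste0("r", i), condition = cond)
        })
        ensembles[[cond]] <- new_ensemble(trajs)
      }
    }
    log_stage("simulate", sprintf("%d condition(s): %s",
                                  length(ensembles),
                                  paste(names(ensembles), collapse = ", ")))
  }, error = function(e) fail("simulate", e))
  results$ensembles <- ensembles
  results$truths <- truths

  equil_masks <- lapply(ensembles, function(ens) {
    lapply(ens$trajectories, frames_in, from_ns = config$equil_ns)
  })

  # -- hbonds ------------------------------------------------------------
  hb_specs <- lapply(names(ensembles), function(cond) {
    cc <- config$conditions[[cond]]
    if (!is.null(cc$spec)) truths[[cond]]$hbonds else cc$hbonds
  })
  names(hb_specs) <- names(ensembles)
  traces <- list()
  if ("hbonds" %in% config$stages) {
    tryCatch({
      for (cond in names(ensembles)) {
        if (is.null(hb_specs[[cond]])) {
          stop("no H-bond table for condition ", cond)
        }
        traces[[cond]] <- detect_hbonds_ensemble(ensembles[[cond]],
                                                 hb_specs[[cond]])
        prob <- hbond_probability(traces[[cond]],
                                  frame_mask = equil_masks[[cond]])
        write.table(prob, file.path(out_dir,
                                    paste0("hbond_occupancy_", cond, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      log_stage("hbonds", sprintf("%d bond(s) per condition",
                                  length(traces[[1]][[1]]$labels)))
    }, error = function(e) fail("hbonds", e))
  }
  results$traces <- traces

  # -- bind --------------------------------------------------------------
  bindings <- list(); bound_masks <- list()
  if ("bind" %in% config$stages && length(traces)) {
    tryCatch({
      for (cond in names(traces)) {
        bindings[[cond]] <- lapply(traces[[cond]], classify_binding,
                                   persistence = config$persistence,
                                   allow_rebinding = config$allow_rebinding)
        bound_masks[[cond]] <- lapply(seq_along(bindings[[cond]]),
                                      function(r) {
          intersect(bound_frames(bindings[[cond]][[r]]),
                    equil_masks[[cond]][[r]])
        })
        st <- do.call(rbind, lapply(names(bindings[[cond]]), function(r) {
          data.frame(replica = r,
                     frame = seq_along(bindings[[cond]][[r]]$state),
                     state = bindings[[cond]][[r]]$state)
        }))
        write.table(st, file.path(out_dir,
                                  paste0("binding_states_", cond, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(config$termination_pairs)) {
          term <- lapply(ensembles[[cond]]$trajectories, termination_metric,
                         pairs = config$termination_pairs,
                         threshold = config$termination_threshold)
          tf <- data.frame(
            replica = names(term),
            termination_frame = vapply(term, function(x)
              as.integer(x$termination_frame), integer(1)))
          write.table(tf, file.path(out_dir,
                                    paste0("termination_", cond, ".tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          results$termination[[cond]] <- term
        }
      }
      nb <- vapply(bound_masks, function(m) sum(lengths(m)), numeric(1))
      log_stage("bind", paste("bound frames:",
                              paste(names(nb), nb, collapse = ", ")))
    }, error = function(e) fail("bind", e))
  }
  results$bindings <- bindings
  results$bound_masks <- bound_masks

  masks_for <- function(cond) {
    if (length(bound_masks)) bound_masks[[cond]] else equil_masks[[cond]]
  }

  # -- geometry ----------------------------------------------------------
  if ("geometry" %in% config$stages) {
    tryCatch({
      core <- if (!is.null(config$core_residues)) {
        config$core_residues
      } else {
        combined <- new_ensemble(unlist(lapply(ensembles, function(e)
          e$trajectories), recursive = FALSE))
        find_stable_core(combined, n_clusters = config$core_clusters)
      }
      results$core <- core
      avgs <- list()
      for (cond in names(ensembles)) {
        avgs[[cond]] <- average_structure(ensembles[[cond]], core = core,
                                          frame_masks = masks_for(cond))
        write_structure(avgs[[cond]]$top, avgs[[cond]]$xyz,
                        file.path(out_dir, paste0("average_", cond, ".pdb")),
                        rmsf = avgs[[cond]]$rmsf)
      }
      results$averages <- avgs
      if (length(ensembles) >= 2) {
        cn <- names(ensembles)[1:2]
        ddm <- distance_difference_map(
          ensembles[[cn[1]]], ensembles[[cn[2]]],
          frame_masksA = masks_for(cn[1]), frame_masksB = masks_for(cn[2]))
        write.table(ddm$blocks,
                    file.path(out_dir, "distance_difference_blocks.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        results$ddmap <- ddm
        top <- ensembles[[1]]$trajectories[[1]]$top
        mobile <- residue_ids_of_domain(top, "PP")
        if (length(mobile) >= 10) {
          hs <- hinge_scan(avgs[[cn[1]]], avgs[[cn[2]]], mobile = mobile)
          write.table(as.data.frame(hs),
                      file.path(out_dir, "hinge_scan.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          results$hinge <- hs
        }
      }
      if (!is.null(config$latch_pairs)) {
        lh <- latch_distance_histograms(
          ensembles, config$latch_pairs,
          frame_masks = setNames(lapply(names(ensembles), masks_for),
                                 names(ensembles)))
        results$latch <- lh
      }
      ncore <- if (inherits(core, "stable_core")) length(core$residues)
               else length(core)
      log_stage("geometry", sprintf("core of %d residues", ncore))
    }, error = function(e) fail("geometry", e))
  }

  # -- energy ------------------------------------------------------------
  if ("energy" %in% config$stages && !is.null(config$energy)) {
    tryCatch({
      for (cond in names(ensembles)) {
        top <- ensembles[[cond]]$trajectories[[1]]$top
        ga <- select_atoms(top, config$energy$groupA)
        gb <- select_atoms(top, config$energy$groupB)
        per_rep <- vapply(seq_along(ensembles[[cond]]$trajectories),
                          function(r) {
          tr <- ensembles[[cond]]$trajectories[[r]]
          mask <- masks_for(cond)[[r]]
          # subsample long masks for the pairwise sums
          if (length(mask) > 200) {
            mask <- mask[seq(1, length(mask), length.out = 200)]
          }
          dec <- interaction_energy(tr, ga, gb, frame_mask = mask,
                                    prefilter_com = config$energy$prefilter)
          mean(dec$total)
        }, numeric(1))
        jk <- if (length(per_rep) >= 3) jackknife_check(per_rep) else NULL
        write.table(
          data.frame(replica = names(ensembles[[cond]]$trajectories),
                     mean_energy = per_rep),
          file.path(out_dir, paste0("interaction_energy_", cond, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        results$energy[[cond]] <- list(per_replica = per_rep,
                                       jackknife = jk)
      }
      log_stage("energy", "per-replica interaction energies written")
    }, error = function(e) fail("energy", e))
  }

  # -- pca ---------------------------------------------------------------
  if ("pca" %in% config$stages) {
    tryCatch({
      combined <- new_ensemble(unlist(lapply(ensembles, function(e)
        e$trajectories), recursive = FALSE))
      all_masks <- unlist(lapply(names(ensembles), masks_for),
                          recursive = FALSE)
      model <- cartesian_pca(combined, core = results$core,
                             exclude_residues = config$pca_exclude,
                             frame_masks = all_masks)
      results$pca <- model
      nrep <- vapply(names(ensembles), function(cond)
        length(ensembles[[cond]]$trajectories), integer(1))
      nfr <- vapply(unname(unlist(lapply(names(ensembles), masks_for),
                                  recursive = FALSE)), length, integer(1))
      cond_of_frame <- rep(rep(names(ensembles), nrep), nfr)
      proj <- lapply(setNames(names(ensembles), names(ensembles)),
                     function(cond) {
        model$projections[cond_of_frame == cond, 1:2, drop = FALSE]
      })
      results$projection_density <- projection_density(proj)
      for (cond in names(ensembles)) {
        cc <- cross_correlation(ensembles[[cond]], core = results$core,
                                frame_masks = masks_for(cond))
        results$cross_correlation[[cond]] <- cc
        write.table(round(cc$C, 6),
                    file.path(out_dir, paste0("cross_correlation_",
                                              cond, ".tsv")),
                    sep = "\t", quote = FALSE)
      }
      log_stage("pca", sprintf("PC1 %.1f%%, PC2 %.1f%% of variance",
                               100 * model$var_fraction[1],
                               100 * model$var_fraction[2]))
    }, error = function(e) fail("pca", e))
  }

  # -- network -----------------------------------------------------------
  if ("network" %in% config$stages &&
      length(results$cross_correlation)) {
    tryCatch({
      for (cond in names(ensembles)) {
        net <- build_network(results$cross_correlation[[cond]],
                             threshold = config$network_threshold)
        results$networks[[cond]] <- net
        write_network_tsv(net, file.path(out_dir,
                                         paste0("network_", cond, ".tsv")))
        write_network_graphml(net, file.path(out_dir,
                                             paste0("network_", cond,
                                                    ".graphml")))
        if (igraph::ecount(net$graph)) {
          part <- detect_communities(net)
          results$communities[[cond]] <- part
          results$community_graphs[[cond]] <-
            community_graph(part, net, variant = "simplified")
          cent <- network_centrality(net)
          write.table(cent, file.path(out_dir,
                                      paste0("centrality_", cond, ".tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          results$centrality[[cond]] <- cent
        }
        if (!is.null(config$sources) && !is.null(config$sinks)) {
          src <- intersect(as.character(config$sources), net$nodes)
          snk <- intersect(as.character(config$sinks), net$nodes)
          ps <- withCallingHandlers(
            suboptimal_paths(net, src, snk, k = config$n_paths),
            warning = function(w) invokeRestart("muffleWarning"))
          results$paths[[cond]] <- ps
          write_paths_tsv(ps, file.path(out_dir,
                                        paste0("paths_", cond, ".tsv")))
        }
      }
      log_stage("network", sprintf(
        "edges: %s",
        paste(names(results$networks), vapply(results$networks, function(n)
          igraph::ecount(n$graph), numeric(1)), collapse = ", ")))
    }, error = function(e) fail("network", e))
  }

  # -- report ------------------------------------------------------------
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("report", sprintf("%d output file(s)", nrow(manifest)))
  structure(list(stages = stages, config = config, out_dir = out_dir,
                 manifest = manifest, results = results),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run:", paste(x$stages, collapse = " -> "), "\n")
  cat("outputs in", x$out_dir, ":", nrow(x$manifest), "file(s)\n")
  invisible(x)
}
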