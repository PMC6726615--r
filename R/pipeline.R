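#' Pipeline configuration
#'
#' Controls the iterative predict–build–reseed loop: 3 iterations by
#' default (more rarely help), an ensemble per iteration, greedy
#' TM-score leader clustering of each ensemble, and selection of a
#' representative from the largest cluster.
#'
#' @param iterations Iteration count (>= 1, default 3).
#' @param cluster_threshold TM-score threshold for joining a cluster
#'   (default 0.6).
#' @param builder A [builder_config()] (its `ensemble_size` is the
#'   per-iteration ensemble size).
#' @param rng_seed Integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(iterations = 3L, cluster_threshold = 0.6,
                            builder = builder_config(), rng_seed = 1L) {
  stopifnot(iterations >= 1)
  structure(list(iterations = as.integer(iterations),
                 cluster_threshold = cluster_threshold,
                 builder = builder, rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Cluster an ensemble by structural similarity
#'
#' Greedy leader clustering on pairwise TM-score: models are visited in
#' ensemble order and join the first cluster whose leader they match at
#' TM >= `threshold`, otherwise they found a new cluster.  Clusters are
#' ordered by size, then by leader energy.
#'
#' @param e An `ensemble` from [build_ensemble()].
#' @param threshold TM-score threshold (default 0.6).
#' @return A list of integer vectors of model indices; the first element
#'   of each vector is the cluster leader.
#' @export
cluster_ensemble <- function(e, threshold = 0.6) {
  stopifnot(inherits(e, "ensemble"), length(e$models) >= 1)
  leaders <- integer(0)
  members <- list()
  for (k in seq_along(e$models)) {
    placed <- FALSE
    for (c in seq_along(leaders)) {
      if (tm_score(e$models[[k]], e$models[[leaders[c]]]) >= threshold) {
        members[[c]] <- c(members[[c]], k); placed <- TRUE; break
      }
    }
    if (!placed) {
      leaders <- c(leaders, k)
      members[[length(leaders)]] <- k
    }
  }
  en <- vapply(e$models, function(m) m$energy$total, 0)
  ord <- order(-lengths(members), en[leaders])
  members[ord]
}

# internal quality score standing in for external statistical potentials:
# restraint-violation energy plus clash energy (lower is better)
model_quality_score <- function(m) {
  en <- m$energy
  en$distance + en$hbond + en$torsion + en$chirality + en$clash
}

#' Select the representative model of an ensemble
#'
#' Within the largest cluster, the member with the lowest internal
#' quality score (restraint-violation energy plus clash energy) is
#' returned; ties break by total energy, then by ensemble index.
#'
#' @param e An `ensemble`.
#' @param clusters Output of [cluster_ensemble()].
#' @return A [fold_model()].
#' @export
select_representative <- function(e, clusters) {
  stopifnot(length(clusters) >= 1)
  top <- clusters[[1]]
  q <- vapply(e$models[top], model_quality_score, 0)
  en <- vapply(e$models[top], function(m) m$energy$total, 0)
  e$models[[top[order(q, en, top)[1]]]]
}

#' Run the iterative predict-build-reseed pipeline
#'
#' Iteration 1 calls the predictor unseeded and derives distance,
#' H-bond and torsion restraints; torsion restraints are computed once
#' here and reused in every later iteration.  Each subsequent iteration
#' passes the previous representative model to the predictor (which
#' conditions on its Cβ–Cβ distance matrix), regenerates the distance
#' and H-bond restraints, rebuilds an ensemble and reselects a
#' representative.  The final representative, the last ensemble, and a
#' per-iteration trace are returned.  A predictor failure aborts with
#' the partial trace attached to the error condition.
#'
#' @param target A list with `sequence` (string) and `predictor` (a
#'   function of an optional seed [fold_model()] returning `distogram`,
#'   `hbond_map`, `torsions`; see [oracle_predictor()]).
#' @param cfg A [pipeline_config()].
#' @param native Optional reference [fold_model()]; when supplied each
#'   iteration's representative is scored by TM-score in the trace.
#' @param bound_threshold,hbond_threshold Restraint-derivation
#'   likelihood thresholds.
#' @return A list of class `pipeline_result`: `model` (final
#'   representative), `ensemble` (final iteration's full ensemble),
#'   `trace` (data.frame: iteration, restraint counts, cluster count,
#'   best/median energy, TM-score when native given),
#'   `representatives` (the per-iteration seed models) and `torsions`
#'   (the reused restraints).
#' @export
run_pipeline <- function(target, cfg = pipeline_config(), native = NULL,
                         bound_threshold = 0.4, hbond_threshold = 0.85) {
  stopifnot(is.function(target$predictor), is.character(target$sequence))
  trace <- list()
  reps <- list()
  seed_model <- NULL
  torsion_rs <- NULL
  final <- NULL
  ens <- NULL
  for (it in seq_len(cfg$iterations)) {
    pred <- tryCatch(target$predictor(seed_model), error = function(e) {
      stop(structure(class = c("pipeline_abort", "error", "condition"),
                     list(message = sprintf(
                       "predictor failed at iteration %d: %s", it,
                       conditionMessage(e)),
                       call = sys.call(-1),
                       trace = do.call(rbind, trace))))
    })
    bounds <- distogram_to_bounds(pred$distogram,
                                  threshold = bound_threshold)
    hbonds <- hbond_map_to_restraints(pred$hbond_map,
                                      threshold = hbond_threshold)
    if (it == 1L)  # single set of dihedral restraints, reused throughout
      torsion_rs <- torsions_to_restraints(pred$torsions)
    rs <- restraint_set(bounds, hbonds, torsion_rs, target$sequence,
                        meta = list(iteration = it,
                                    bound_threshold = bound_threshold,
                                    hbond_threshold = hbond_threshold))
    bcfg <- cfg$builder
    bcfg$rng_seed <- cfg$rng_seed + 131L * it
    ens <- build_ensemble(rs, bcfg)
    clusters <- cluster_ensemble(ens, cfg$cluster_threshold)
    rep_model <- select_representative(ens, clusters)
    en <- vapply(ens$models, function(m) m$energy$total, 0)
    trace[[it]] <- data.frame(
      iteration = it, n_bounds = nrow(bounds), n_hbonds = nrow(hbonds),
      n_torsions = nrow(torsion_rs), n_clusters = length(clusters),
      best_energy = min(en), median_energy = stats::median(en),
      tm = if (!is.null(native)) tm_score(rep_model, native) else NA_real_)
    seed_model <- rep_model
    reps[[it]] <- rep_model
    final <- rep_model
  }
  structure(list(model = final, ensemble = ens,
                 trace = do.call(rbind, trace),
                 representatives = reps, torsions = torsion_rs,
                 config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d iteration(s)\n", nrow(x$trace)))
  print(x$trace, row.names = FALSE)
  invisible(x)
}
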