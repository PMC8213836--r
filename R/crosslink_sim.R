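#' Saturate a lever field with crosslinker molecules
#'
#' Runs the sequential saturation-binding rule: each lever starts with two
#' free binding sites; molecules are introduced one by one, each binding a
#' random lever with a free site and then the closest \emph{other} lever
#' with a free site within the molecule's reach (ties broken by lowest
#' lever index); if no reachable partner exists the molecule is left singly
#' bound. Molecules keep being introduced until every binding site on the
#' surface is occupied.
#'
#' @param field A `lever_field` from [place_levers()].
#' @param spec A `crosslinker_spec`; its [max_reach()] defines which lever
#'   pairs can be bridged.
#' @param seed Integer seed for the binding order.
#' @param initial_draw How the first lever of each molecule is drawn:
#'   `"lever"` (default) — uniform over levers with at least one free
#'   site; `"site"` — uniform over free sites, so levers with two free
#'   sites are twice as likely.
#' @return An object of class `binding_state`: a list with `molecules`
#'   (data frame `molecule_id`, `lever_a`, `lever_b`, `lever_b` `NA` for
#'   singly bound), `bridges` (the \emph{set} of distinct unordered lever
#'   pairs connected by at least one doubly bound molecule; a pair bridged
#'   by two molecules appears once), `free_sites` (all zero at
#'   saturation), `n_levers`, and the `spec` and `seed` used.
#' @examples
#' g <- build_hex_grid(500)
#' f <- place_levers(g, 100, seed = 1)
#' s <- saturate_binding(f, crosslinker_preset("441"), seed = 2)
#' interlinked_fraction(s)
#' @export
saturate_binding <- function(field, spec, seed,
                             initial_draw = c("lever", "site")) {
  stopifnot(inherits(field, "lever_field"), inherits(spec, "crosslinker_spec"))
  initial_draw <- match.arg(initial_draw)
  n <- nrow(field$anchors)
  if (n == 0) stop_invalid("lever field is empty")
  reach <- max_reach(spec)
  res <- with_seed(seed, cpp_saturate(field$anchors[, 1], field$anchors[, 2],
                                      reach, initial_draw == "site"))
  molecules <- data.frame(molecule_id = seq_along(res$lever_a),
                          lever_a = res$lever_a,
                          lever_b = res$lever_b)
  doubly <- !is.na(molecules$lever_b)
  bridges <- unique(cbind(
    pmin(molecules$lever_a[doubly], molecules$lever_b[doubly]),
    pmax(molecules$lever_a[doubly], molecules$lever_b[doubly])))
  colnames(bridges) <- c("lever_a", "lever_b")
  structure(
    list(molecules = molecules,
         bridges = bridges,
         free_sites = integer(n),
         n_levers = n,
         spec = spec,
         seed = as.integer(seed)),
    class = "binding_state"
  )
}

#' @export
print.binding_state <- function(x, ...) {
  cat(sprintf(
    "<binding_state> %d levers, %d molecules (%d bridges), fraction interlinked %.3f\n",
    x$n_levers, nrow(x$molecules), nrow(x$bridges), interlinked_fraction(x)))
  invisible(x)
}

#' Fraction of levers interlinked through bound molecules
#'
#' A lever counts as interlinked if it is incident to at least one bridge,
#' i.e. connected to at least one other lever by a doubly bound molecule.
#' Chains count: every lever in a chain of bridges is interlinked.
#'
#' @param state A `binding_state` from [saturate_binding()].
#' @return Proportion in `[0, 1]`.
#' @export
interlinked_fraction <- function(state) {
  stopifnot(inherits(state, "binding_state"))
  if (state$n_levers == 0) stop_invalid("binding state has no levers")
  length(unique(c(state$bridges))) / state$n_levers
}

#' Default surface side for a target density and binder reach
#'
#' Large enough that boundary effects on the interlinked fraction are
#' negligible: at least 2.4 um, and at least 12 times the sum of the mean
#' lever distance and the binder reach.
#'
#' @param mean_distance_nm Mean inter-lever distance in nm.
#' @param reach_nm Binder reach in nm.
#' @return Side length in nm.
#' @export
default_side_nm <- function(mean_distance_nm, reach_nm) {
  max(2400, 12 * (mean_distance_nm + reach_nm))
}

#' Replicate the saturation simulation over surfaces and binding orders
#'
#' Generates `n_surfaces` independent lever fields and, on each, runs the
#' saturation binding `n_repeats` times with fresh binding orders,
#' recording the interlinked fraction of each replicate. Surface and
#' repeat indices are mixed into the seeds via [derive_seed()], so the
#' whole experiment is reproducible from `base_seed` alone.
#'
#' @param mean_distance_nm Target mean inter-lever distance in nm.
#' @param spec A `crosslinker_spec`.
#' @param n_surfaces,n_repeats Replication counts (default 10 x 10).
#' @param base_seed Integer base seed.
#' @param side_nm Surface side in nm; default [default_side_nm()].
#' @param in_radius_nm Tessellation in-radius in nm (default 2.5).
#' @param initial_draw Passed to [saturate_binding()].
#' @return An object of class `crosslink_result`: a list with `replicates`
#'   (data frame `surface`, `repeat_idx`, `fraction_interlinked`,
#'   `n_levers`, `n_molecules`, `n_bridges`), `mean`, `sd`, `n`, and the
#'   run parameters.
#' @examples
#' \donttest{
#' r <- run_replicates(200, crosslinker_preset("441"),
#'                     n_surfaces = 2, n_repeats = 2, base_seed = 1)
#' r$mean
#' }
#' @export
run_replicates <- function(mean_distance_nm, spec, n_surfaces = 10,
                           n_repeats = 10, base_seed = 1, side_nm = NULL,
                           in_radius_nm = 2.5,
                           initial_draw = c("lever", "site")) {
  stopifnot(inherits(spec, "crosslinker_spec"))
  initial_draw <- match.arg(initial_draw)
  if (n_surfaces < 1 || n_repeats < 1) {
    stop_invalid("n_surfaces and n_repeats must be at least 1")
  }
  reach <- max_reach(spec)
  if (is.null(side_nm)) side_nm <- default_side_nm(mean_distance_nm, reach)
  grid <- build_hex_grid(side_nm, in_radius_nm)
  rows <- vector("list", n_surfaces * n_repeats)
  k <- 0L
  for (s in seq_len(n_surfaces)) {
    field <- place_levers(grid, mean_distance_nm,
                          seed = derive_seed(base_seed, "surface", s))
    for (r in seq_len(n_repeats)) {
      state <- saturate_binding(field, spec,
                                seed = derive_seed(base_seed, "binding", s, r),
                                initial_draw = initial_draw)
      k <- k + 1L
      rows[[k]] <- data.frame(
        surface = s, repeat_idx = r,
        fraction_interlinked = interlinked_fraction(state),
        n_levers = state$n_levers,
        n_molecules = nrow(state$molecules),
        n_bridges = nrow(state$bridges))
    }
  }
  replicates <- do.call(rbind, rows)
  structure(
    list(replicates = replicates,
         mean = mean(replicates$fraction_interlinked),
         sd = sd(replicates$fraction_interlinked),
         n = nrow(replicates),
         spec = spec,
         mean_distance_nm = mean_distance_nm,
         side_nm = side_nm,
         in_radius_nm = in_radius_nm,
         base_seed = as.integer(base_seed)),
    class = "crosslink_result"
  )
}

#' @export
print.crosslink_result <- function(x, ...) {
  cat(sprintf(
    "<crosslink_result> %s at d = %g nm: mean fraction %.3f (sd %.3f, n = %d)\n",
    x$spec$name, x$mean_distance_nm, x$mean, x$sd, x$n))
  invisible(x)
}

#' Interlinking curve over binder architectures and surface densities
#'
#' Full factorial sweep of [run_replicates()] over a list of binder specs
#' and mean inter-lever distances, summarising the interlinked fraction
#' per cell.
#'
#' @param specs List of `crosslinker_spec` objects (default: the three
#'   presets).
#' @param distances Mean inter-lever distances in nm (default 50, 100,
#'   200).
#' @param ... Passed to [run_replicates()] (replication counts, seeds,
#'   side).
#' @return A data frame of class `crosslink_curve` with one row per
#'   (spec, distance): `spec`, `mean_distance_nm`, `mean`, `sd`, `n`;
#'   per-replicate values are kept in the `"replicates"` attribute
#'   (columns `spec`, `mean_distance_nm`, `replicate`,
#'   `fraction_interlinked`).
#' @export
crosslink_curve <- function(specs = lapply(c("441", "841", "mAb_combo"),
                                           crosslinker_preset),
                            distances = c(50, 100, 200), ...) {
  if (inherits(specs, "crosslinker_spec")) specs <- list(specs)
  if (any(!vapply(specs, inherits, logical(1), "crosslinker_spec"))) {
    stop_invalid("specs must be crosslinker_spec objects")
  }
  if (any(distances <= 0)) stop_invalid("distances must be positive")
  summaries <- list()
  reps <- list()
  for (spec in specs) {
    for (d in distances) {
      res <- run_replicates(d, spec, ...)
      summaries[[length(summaries) + 1L]] <- data.frame(
        spec = spec$name, mean_distance_nm = d,
        mean = res$mean, sd = res$sd, n = res$n)
      reps[[length(reps) + 1L]] <- data.frame(
        spec = spec$name, mean_distance_nm = d,
        replicate = seq_len(res$n),
        fraction_interlinked = res$replicates$fraction_interlinked)
    }
  }
  out <- do.call(rbind, summaries)
  attr(out, "replicates") <- do.call(rbind, reps)
  class(out) <- c("crosslink_curve", "data.frame")
  out
}

#' Write a crosslinking curve as CSV
#'
#' Writes the per-replicate table
#' (`spec,mean_distance_nm,replicate,fraction_interlinked`) to `path` and
#' the summary (`spec,mean_distance_nm,mean,sd,n`) to a `_summary.csv`
#' sibling file.
#'
#' @param curve A `crosslink_curve`.
#' @param path Output CSV path for the per-replicate table.
#' @return `path`, invisibly.
#' @export
write_crosslink_curve <- function(curve, path) {
  stopifnot(inherits(curve, "crosslink_curve"))
  write.csv(attr(curve, "replicates"), path, row.names = FALSE)
  summary_path <- sub("\\.csv$", "_summary.csv", path)
  if (identical(summary_path, path)) summary_path <- paste0(path, "_summary.csv")
  write.csv(as.data.frame(curve), summary_path, row.names = FALSE)
  invisible(path)
}
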