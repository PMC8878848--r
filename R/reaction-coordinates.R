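#' Atom selection for reaction coordinates
#'
#' Identifies, by particle index, the ligand copies and the binding-site atoms
#' whose centres of mass define the binding coordinate. COM weights default to
#' unit weights over the selected (carbon-like) sites; pass per-particle
#' masses for mass weighting.
#'
#' @param ligand list of integer index vectors, one per ligand copy.
#' @param site integer index vector for the binding-site atoms.
#' @param weights optional positive per-particle weights (full-length vector,
#'   indexed by the selection); NULL means unit weights.
#' @return an object of class `atom_selection`.
#' @export
atom_selection <- function(ligand, site, weights = NULL) {
  if (!is.list(ligand)) ligand <- list(ligand)
  ligand <- lapply(ligand, as.integer)
  site <- as.integer(site)
  if (length(site) == 0 || any(lengths(ligand) == 0))
    stop("ligand and site selections must be non-empty")
  if (length(intersect(unlist(ligand), site)) > 0)
    stop("ligand and site selections must be disjoint")
  if (!is.null(weights) && any(weights <= 0)) stop("weights must be > 0")
  structure(list(ligand = ligand, site = site, weights = weights),
            class = "atom_selection")
}

#' Build the default selection from a system state
#'
#' One ligand selection per distinct copy label, plus the site-marker
#' particles as the binding-site selection.
#' @param state a [system_state()].
#' @return an [atom_selection()].
#' @export
selection_from_state <- function(state) {
  ids <- sort(unique(state$copy_id[state$copy_id > 0L]))
  atom_selection(ligand = lapply(ids, function(k) which(state$copy_id == k)),
                 site = which(state$copy_id == 0L))
}

#' Reaction-coordinate specification
#'
#' @param kind one of `"d_com"`, `"rmsd_to_product"`, `"delta_matrix"`,
#'   `"radius_of_gyration"`, `"composite"`.
#' @param selection an [atom_selection()] (required for all kinds but
#'   composite).
#' @param reference coordinate matrix of the product (bound) structure;
#'   required for `rmsd_to_product` and `delta_matrix`.
#' @param components for composite: list of component `rc_spec`s.
#' @param weights for composite: non-negative weights, not all zero.
#' @param copy_reduction how a multi-copy snapshot is scored: `"min"` (the
#'   best copy, the default — any copy binding terminates the search) or
#'   `"per_copy"` (rank every (snapshot, copy) pair separately).
#' @param normalize for composite: `"zscore"` (components standardised over
#'   the snapshot pool being ranked) or `"none"` (raw weighted sum).
#' @return an object of class `rc_spec`.
#' @export
rc_spec <- function(kind, selection = NULL, reference = NULL,
                    components = NULL, weights = NULL,
                    copy_reduction = c("min", "per_copy"),
                    normalize = c("zscore", "none")) {
  kind <- match.arg(kind, c("d_com", "rmsd_to_product", "delta_matrix",
                            "radius_of_gyration", "composite"))
  copy_reduction <- match.arg(copy_reduction)
  normalize <- match.arg(normalize)
  if (kind %in% c("rmsd_to_product", "delta_matrix") && is.null(reference))
    stop(sprintf("rc kind '%s' requires a reference structure", kind))
  if (kind == "composite") {
    if (is.null(components) || length(components) == 0)
      stop("composite rc requires components")
    if (is.null(weights) || length(weights) != length(components))
      stop("composite rc requires one weight per component")
    if (any(weights < 0) || all(weights == 0))
      stop("composite weights must be >= 0 and not all zero")
  }
  structure(list(kind = kind, selection = selection, reference = reference,
                 components = components, weights = weights,
                 copy_reduction = copy_reduction, normalize = normalize),
            class = "rc_spec")
}

#' Weighted centre of mass
#' @param coords m x 3 coordinate matrix.
#' @param weights positive weights, recycled unit weights if NULL.
#' @return 3-vector sum(w_i x_i) / sum(w_i).
#' @export
center_of_mass <- function(coords, weights = NULL) {
  coords <- rbind(coords)
  if (nrow(coords) == 0) stop("empty selection: no coordinates")
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  if (length(weights) != nrow(coords) || any(weights <= 0))
    stop("weights must be positive, one per coordinate row")
  colSums(coords * weights) / sum(weights)
}

#' Ligand-to-site centre-of-mass distance
#'
#' The binding coordinate: Euclidean distance between the COM of one ligand
#' copy and the COM of the binding-site selection.
#'
#' @param coords full n x 3 coordinate matrix of the snapshot.
#' @param selection an [atom_selection()].
#' @param copy which ligand copy (index into `selection$ligand`).
#' @return scalar distance.
#' @export
d_com <- function(coords, selection, copy = 1L) {
  if (copy < 1 || copy > length(selection$ligand))
    stop(sprintf("no ligand copy %d in selection (have %d)", copy,
                 length(selection$ligand)))
  li <- selection$ligand[[copy]]
  si <- selection$site
  w <- selection$weights
  com_l <- center_of_mass(coords[li, , drop = FALSE],
                          if (is.null(w)) NULL else w[li])
  com_s <- center_of_mass(coords[si, , drop = FALSE],
                          if (is.null(w)) NULL else w[si])
  sqrt(sum((com_l - com_s)^2))
}

# Kabsch optimal superposition: proper rotation + translation of b onto a
kabsch_fit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(B %*% t(R), 2, ca, `+`)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' With `superpose = TRUE`, `coords_b` is first fitted onto `coords_a` by the
#' optimal least-squares rigid motion (Kabsch algorithm, proper rotations
#' only), which is the RMSD-to-product coordinate used to steer sampling
#' toward a known bound structure.
#'
#' @param coords_a,coords_b m x 3 coordinate matrices with matched rows.
#' @param superpose fit before measuring?
#' @return scalar RMSD.
#' @export
rmsd <- function(coords_a, coords_b, superpose = FALSE) {
  coords_a <- rbind(coords_a); coords_b <- rbind(coords_b)
  if (!identical(dim(coords_a), dim(coords_b)))
    stop("coordinate sets must have the same number of points")
  if (superpose) {
    if (nrow(coords_a) < 3) stop("superposition requires >= 3 points")
    coords_b <- kabsch_fit(coords_a, coords_b)
  }
  sqrt(sum((coords_a - coords_b)^2) / nrow(coords_a))
}

#' Distance-matrix difference score
#'
#' Sum of absolute differences between the pairwise-distance matrices of the
#' instantaneous and reference structures over the selected atoms, each
#' unordered pair counted once. A rotation- and translation-invariant measure
#' of how far the selected geometry is from the target complex.
#'
#' @param coords instantaneous full coordinate matrix.
#' @param reference reference full coordinate matrix.
#' @param indices atom indices valid in both structures.
#' @return scalar score (0 iff all selected pairwise distances agree).
#' @export
delta_matrix_score <- function(coords, reference, indices = seq_len(nrow(coords))) {
  if (length(indices) < 2) stop("delta-matrix score requires >= 2 atoms")
  da <- stats::dist(coords[indices, , drop = FALSE])
  db <- stats::dist(reference[indices, , drop = FALSE])
  sum(abs(da - db))
}

#' Radius of gyration
#' @param coords m x 3 coordinate matrix.
#' @param weights optional positive weights.
#' @return scalar sqrt(sum w_i |x_i - COM|^2 / sum w_i).
#' @export
radius_of_gyration <- function(coords, weights = NULL) {
  coords <- rbind(coords)
  com <- center_of_mass(coords, weights)
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  sqrt(sum(weights * rowSums(sweep(coords, 2, com)^2)) / sum(weights))
}

rc_percopy <- function(coords, spec) {
  sel <- spec$selection
  vapply(seq_along(sel$ligand), function(k) {
    switch(spec$kind,
      d_com = d_com(coords, sel, k),
      rmsd_to_product = {
        li <- sel$ligand[[k]]
        rmsd(spec$reference, coords[li, , drop = FALSE],
             superpose = length(li) >= 3)
      },
      delta_matrix = delta_matrix_score(coords, spec$reference,
                                        c(sel$ligand[[k]], sel$site)),
      radius_of_gyration = {
        li <- sel$ligand[[k]]
        w <- if (is.null(sel$weights)) NULL else sel$weights[li]
        radius_of_gyration(coords[li, , drop = FALSE], w)
      },
      stop("per-copy evaluation undefined for kind ", spec$kind))
  }, numeric(1))
}

#' Evaluate a reaction coordinate on a pool of snapshots
#'
#' The engine ranks whole snapshots, so multi-copy snapshots are reduced to a
#' single score: by default the minimum over copies (any copy binding counts).
#' Composite coordinates are weighted sums of their components, standardised
#' over this pool when `normalize = "zscore"` (a pool of one, or a constant
#' component, standardises to zero).
#'
#' @param snapshots list of snapshots (as from [run_segment()]).
#' @param spec an [rc_spec()].
#' @return numeric vector of scores, one per snapshot.
#' @export
evaluate_rc_pool <- function(snapshots, spec) {
  if (spec$kind != "composite" && is.null(spec$selection))
    spec$selection <- selection_from_state(snapshots[[1]]$state)
  if (spec$kind == "composite") {
    comp <- vapply(seq_along(spec$components), function(k) {
      v <- evaluate_rc_pool(snapshots, spec$components[[k]])
      if (spec$normalize == "zscore") {
        s <- stats::sd(v)
        if (length(v) < 2 || !is.finite(s) || s == 0) v <- rep(0, length(v))
        else v <- (v - mean(v)) / s
      }
      v
    }, numeric(length(snapshots)))
    comp <- rbind(comp)
    return(as.numeric(comp %*% spec$weights))
  }
  vapply(snapshots, function(sn) {
    min(rc_percopy(sn$state$positions, spec))
  }, numeric(1))
}

#' Evaluate a reaction coordinate on one snapshot
#' @param snap a snapshot.
#' @param spec an [rc_spec()].
#' @return scalar score.
#' @export
evaluate_rc <- function(snap, spec) {
  evaluate_rc_pool(list(snap), spec)
}

#' Per-copy reaction-coordinate values for one snapshot
#' @param snap a snapshot.
#' @param spec a non-composite [rc_spec()].
#' @return numeric vector, one value per ligand copy.
#' @export
evaluate_rc_copies <- function(snap, spec) {
  if (is.null(spec$selection))
    spec$selection <- selection_from_state(snap$state)
  rc_percopy(snap$state$positions, spec)
}
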