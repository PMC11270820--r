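#' Topology (surface/bulk) configuration
#'
#' A molecule is labeled `surface` when its coordination number — the count
#' of other molecules within `R_c` — is smaller than `cn_threshold`, else
#' `bulk`. The default radius is the molecule radius plus the graph
#' convolution cutoff.
#'
#' @param cn_threshold coordination threshold (default 20).
#' @param molecule_radius molecule radius in Angstrom (default: the bundled
#'   fixture molecule's radius; supply your own for real molecules).
#' @param graph_cutoff graph convolution cutoff (Angstrom).
#' @param R_c explicit coordination radius, overriding
#'   `molecule_radius + graph_cutoff`.
#' @return a `topology_config` object.
#' @export
topology_config <- function(cn_threshold = 20L, molecule_radius = NULL,
                            graph_cutoff = 6, R_c = NULL) {
  if (is.null(molecule_radius)) molecule_radius <- fixture_molecule()$radius
  if (is.null(R_c)) R_c <- molecule_radius + graph_cutoff
  stopifnot(R_c > 0, cn_threshold >= 1)
  structure(list(cn_threshold = as.integer(cn_threshold),
                 molecule_radius = molecule_radius,
                 graph_cutoff = graph_cutoff, R_c = R_c),
            class = "topology_config")
}

#' Coordination number of one molecule
#'
#' Counts the other molecules with center distance at or below `R_c`
#' (Heaviside convention: a neighbor exactly at `R_c` counts).
#'
#' @param positions M x 3 matrix of molecule positions.
#' @param center_id 1-based row index of the center molecule.
#' @param R_c coordination radius (Angstrom).
#' @param cell optional periodic cell (minimum image applied).
#' @return integer coordination number.
#' @export
coordination_number <- function(positions, center_id, R_c, cell = NULL) {
  positions <- as.matrix(positions)
  d <- sweep(positions, 2L, positions[center_id, ])
  if (!is.null(cell)) d <- minimum_image(d, cell)
  dd <- sqrt(rowSums(d * d))
  sum(dd <= R_c) - 1L
}

#' Surface/bulk labels by the coordination-number rule
#'
#' @param positions M x 3 matrix of molecule positions (e.g.
#'   [pv_positions()]).
#' @param config a [topology_config()].
#' @param cell optional periodic cell.
#' @return character vector, `"surface"` or `"bulk"` per molecule.
#' @export
label_topology <- function(positions, config = topology_config(),
                           cell = NULL) {
  positions <- as.matrix(positions)
  cn <- vapply(seq_len(nrow(positions)), function(i)
    coordination_number(positions, i, config$R_c, cell), 0L)
  ifelse(cn < config$cn_threshold, "surface", "bulk")
}

#' Classify every molecule of every frame of a trajectory
#'
#' Runs either classifier over a list of frames and attaches the
#' coordination-number topology label. For the symmetry-function classifier
#' the descriptor set is checked against the hash stored in the model.
#'
#' @param frames list of [simulation_frame()] objects.
#' @param model an `sf_classifier` or `gnn_classifier`.
#' @param template [pv_template()] (symmetry-function route).
#' @param set [descriptor_set()] (symmetry-function route).
#' @param topology a [topology_config()], or `NULL` to skip the topology
#'   column.
#' @param molecule_size atoms per molecule for frames without molecule ids.
#' @return data.frame with one record per molecule per frame:
#'   `frame_index`, `time`, `molecule_id`, `class_label`, `max_prob`,
#'   `tie_flag`, `topology`, and per-class probability columns.
#' @export
classify_trajectory <- function(frames, model, template = NULL, set = NULL,
                                topology = topology_config(),
                                molecule_size = NULL) {
  if (inherits(frames, "simulation_frame")) frames <- list(frames)
  is_sf <- inherits(model, "sf_classifier")
  if (is_sf) {
    if (is.null(template) || is.null(set))
      stop("the symmetry-function route needs a template and descriptor set")
    if (!is.na(model$descriptor_set_hash) &&
        !identical(model$descriptor_set_hash, descriptor_set_hash(set)))
      stop("descriptor set does not match the one the model was trained ",
           "with (hash mismatch)")
  }
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    groups <- group_molecules(fr, molecule_size = molecule_size)
    if (is_sf) {
      pv <- extract_point_vectors(fr, groups, template)
      max_rc <- max(vapply(set$entries, `[[`, 0, "r_c"))
      nl <- build_neighbor_list(pv_positions(pv),
                                if (any(fr$pbc)) fr$cell else NULL, max_rc)
      x <- compute_descriptors(pv, nl, set)
      rec <- classify(model, x,
                      molecule_ids = vapply(groups, `[[`, 0L, "molecule_id"))
      centers <- pv_positions(pv)
    } else {
      rec <- gnn_classify(model, fr)
      ## molecule centers: first atom of each group (the template anchor)
      centers <- do.call(rbind, lapply(groups, function(g)
        fr$positions[g$atom_indices[1], ]))
    }
    if (!is.null(topology)) {
      rec$topology <- label_topology(centers, topology,
                                     if (any(fr$pbc)) fr$cell else NULL)
    }
    rec <- cbind(data.frame(frame_index = fr$frame_index, time = fr$time),
                 rec)
    out[[fi]] <- rec
  }
  do.call(rbind, out)
}

#' Per-frame class composition time series
#'
#' Counts molecules per class and frame, optionally split into
#' low-coordination "surface" and high-coordination "core" groups, with
#' untracked classes collapsed into `"other"`. Counts are conserved: per
#' frame (and group) they sum to the number of molecules in scope.
#'
#' @param records output of [classify_trajectory()] (or any data.frame with
#'   `frame_index`, `time`, `class_label` and optionally `topology`).
#' @param tracked character vector of class labels reported individually;
#'   remaining classes are aggregated as `"other"`. `NULL` tracks all.
#' @param grouping `"all"` or `"core_surface"` (requires a `topology`
#'   column; "core" = bulk).
#' @param molecule_ids optional subset of molecule ids (e.g. from
#'   [region_filter()]) to restrict the analysis to.
#' @return data.frame with `frame_index`, `time`, `group`, `class`,
#'   `count`.
#' @export
class_time_series <- function(records, tracked = NULL,
                              grouping = c("all", "core_surface"),
                              molecule_ids = NULL) {
  grouping <- match.arg(grouping)
  if (!is.null(molecule_ids))
    records <- records[records$molecule_id %in% molecule_ids, , drop = FALSE]
  if (grouping == "core_surface" && is.null(records$topology))
    stop("core_surface grouping needs a topology column")
  cls <- records$class_label
  if (!is.null(tracked)) {
    unknown <- setdiff(tracked, unique(cls))
    ## tracked classes absent from the records are fine (count 0), but a
    ## collapse request naming no known class at all is almost surely a bug
    if (length(unknown) == length(tracked))
      stop("none of the tracked classes occur in the records: ",
           paste(tracked, collapse = ", "))
    cls <- ifelse(cls %in% tracked, cls, "other")
    levels_out <- c(tracked, "other")
  } else levels_out <- sort(unique(cls))
  grp <- if (grouping == "core_surface")
    ifelse(records$topology == "bulk", "core", "surface")
  else rep("all", nrow(records))
  frames <- unique(records[, c("frame_index", "time")])
  out <- list()
  for (i in seq_len(nrow(frames))) {
    sel <- records$frame_index == frames$frame_index[i]
    for (g in unique(grp[sel])) {
      sg <- sel & grp == g
      tab <- table(factor(cls[sg], levels = levels_out))
      out[[length(out) + 1L]] <-
        data.frame(frame_index = frames$frame_index[i],
                   time = frames$time[i], group = g,
                   class = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Select molecules by fractional coordinate along an axis
#'
#' @param frame a periodic [simulation_frame()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param bounds fractional interval within `[0, 1]`.
#' @param position_atom 1-based atom index within each molecule used as the
#'   molecule position.
#' @return integer vector of molecule ids (0-based, matching
#'   [group_molecules()]); empty with a warning if no molecule qualifies.
#' @export
region_filter <- function(frame, axis = c("x", "y", "z"), bounds,
                          position_atom = 1L) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  stopifnot(length(bounds) == 2L, all(bounds >= 0), all(bounds <= 1))
  if (is.null(frame$cell)) stop("region_filter needs a periodic cell")
  groups <- group_molecules(frame)
  centers <- do.call(rbind, lapply(groups, function(g)
    frame$positions[g$atom_indices[position_atom], ]))
  frac <- centers %*% solve(frame$cell)
  f <- frac[, ax] %% 1
  sel <- f >= bounds[1] & f <= bounds[2]
  if (!any(sel)) warning("region_filter selected no molecules")
  vapply(groups, `[[`, 0L, "molecule_id")[sel]
}

#' Confusion matrix and micro F1
#'
#' Micro F1 aggregates over all molecules globally, which for single-label
#' multi-class prediction equals overall accuracy.
#'
#' @param truth true class labels.
#' @param predicted predicted class labels.
#' @param classes optional explicit class ordering.
#' @return list with `confusion` (rows = truth), `micro_f1`, and per-class
#'   `precision`/`recall`.
#' @export
classification_metrics <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  tr <- factor(truth, levels = classes)
  pr <- factor(predicted, levels = classes)
  cm <- table(truth = tr, predicted = pr)
  tp <- diag(cm)
  precision <- tp / pmax(colSums(cm), 1)
  recall <- tp / pmax(rowSums(cm), 1)
  list(confusion = cm, micro_f1 = sum(tp) / sum(cm),
       precision = precision, recall = recall)
}
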