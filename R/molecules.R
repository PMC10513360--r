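#' Bin molecules on a (shifted) Cartesian grid
#'
#' Assigns each molecule at position `x` to bin `floor(x / bin_size - shift)`
#' per dimension (boundary molecules go to the lower-index bin). Empty bins
#' are omitted.
#'
#' @param mol Molecule table (`data.frame` with `x`, `y`, `gene`).
#' @param bin_size Grid spacing in micrometres.
#' @param shift Length-2 shift in grid units, each in `[0, 1)`.
#' @param genes Gene universe for the columns (default: genes present).
#' @return List with `counts` (sparse bins x genes), `coords` (bin centers,
#'   micrometres) and `bin` (bin index per molecule).
#' @export
bin_molecules <- function(mol, bin_size, shift = c(0, 0), genes = NULL) {
  stopifnot(bin_size > 0, length(shift) == 2)
  if (is.null(genes)) genes <- sort(unique(mol$gene))
  ix <- floor(mol$x / bin_size - shift[1])
  iy <- floor(mol$y / bin_size - shift[2])
  key <- paste(ix, iy, sep = "_")
  bins <- sort(unique(key))
  bi <- match(key, bins)
  gi <- match(mol$gene, genes)
  keep <- !is.na(gi)
  counts <- Matrix::sparseMatrix(i = bi[keep], j = gi[keep], x = 1,
                                 dims = c(length(bins), length(genes)),
                                 dimnames = list(bins, genes))
  xy <- do.call(rbind, strsplit(bins, "_"))
  coords <- cbind(x = (as.numeric(xy[, 1]) + shift[1] + 0.5) * bin_size,
                  y = (as.numeric(xy[, 2]) + shift[2] + 0.5) * bin_size)
  rownames(coords) <- bins
  list(counts = .as_sparse(counts), coords = coords, bin = bi)
}

#' Single-molecule annotation configuration
#'
#' @param bin_size Grid spacing in micrometres; should reflect the expected
#'   feature (cell) size, default 10.
#' @param n_shifts Grid shifts per dimension (`n_shifts^2` voting rounds in
#'   2D, shifted in steps of `1/n_shifts` grid spacings).
#' @param annotate_config [annotate_config()] for the per-bin compositional
#'   annotation. Platform normalization is off by default here because the
#'   molecule data and its profile reference share platform effects; the
#'   multi-center booster does not apply (profiles are given directly).
#' @param seed Seed for the stochastic molecule-level assignment.
#' @return List of class `molecule_annotation_config`.
#' @export
molecule_annotation_config <- function(bin_size = 10, n_shifts = 3,
                                       annotate_config = compot::annotate_config(
                                         platform_iterations = 0, multi_center = 0),
                                       seed = 42) {
  stopifnot(bin_size > 0, n_shifts >= 1)
  structure(list(bin_size = bin_size, n_shifts = n_shifts,
                 annotate_config = annotate_config, seed = seed),
            class = "molecule_annotation_config")
}

#' Segmentation-free annotation of single molecules
#'
#' For each of `n_shifts^2` shifted Cartesian grids, molecules are binned,
#' every bin receives a compositional annotation against the reference
#' profiles (bisectioned entropic transport), the bin's counts are split
#' across categories per molecular species (integer split via
#' [split_counts()] rounding), and the per-species category counts are
#' distributed randomly over that species' individual molecules. Each
#' molecule therefore collects one categorical vote per grid; the final
#' label is the modal vote, with ties broken by the highest mean
#' compositional weight over the molecule's bins, then lexicographically.
#'
#' @param mol Molecule table with `x`, `y`, `gene`.
#' @param profiles Genes x categories reference profile matrix (unit column
#'   sums).
#' @param config A [molecule_annotation_config()].
#' @return `mol` with a `category` column; molecules whose gene is absent
#'   from the profiles are dropped with a warning.
#' @export
annotate_molecules <- function(mol, profiles, config = molecule_annotation_config()) {
  known <- mol$gene %in% rownames(profiles)
  if (!all(known)) {
    warning(sum(!known), " molecules with genes absent from the profiles dropped")
    mol <- mol[known, , drop = FALSE]
  }
  n <- nrow(mol)
  cats <- colnames(profiles)
  nshift <- config$n_shifts
  shifts <- expand.grid(sx = seq_len(nshift) - 1, sy = seq_len(nshift) - 1) / nshift
  votes <- matrix(NA_integer_, n, nrow(shifts))
  weight_sum <- matrix(0, n, length(cats))  # mean compositional weight, for ties

  for (s in seq_len(nrow(shifts))) {
    b <- bin_molecules(mol, config$bin_size,
                       shift = c(shifts$sx[s], shifts$sy[s]),
                       genes = rownames(profiles))
    cfg <- config$annotate_config
    prior <- rep(1 / length(cats), length(cats))
    core <- function(x) .ot_core(x, profiles, prior_t = prior,
                                 epsilon = cfg$epsilon, lambda = cfg$lambda,
                                 metric = cfg$metric, max_iter = cfg$max_iter,
                                 tol = cfg$tol)
    comp <- bisection_annotate(core, b$counts, profiles,
                               bisections = cfg$bisections, divisor = cfg$divisor)
    split <- split_counts(b$counts, comp, profiles, round = TRUE,
                          seed = .sub_seed(config$seed, s), max_iter = 5000)
    weight_sum <- weight_sum + comp[b$bin, , drop = FALSE]
    votes[, s] <- .assign_molecule_votes(mol, b$bin, split, profiles,
                                         seed = .sub_seed(config$seed, 1000 + s))
  }

  lab <- integer(n)
  for (i in seq_len(n)) {
    tab <- tabulate(votes[i, ], nbins = length(cats))
    best <- which(tab == max(tab))
    if (length(best) > 1) {
      w <- weight_sum[i, best]
      best <- best[w == max(w)]
    }
    lab[i] <- best[1]  # remaining ties: lexicographic category order
  }
  mol$category <- cats[lab]
  mol
}

# Distribute per-(bin, gene, category) integer split counts randomly over
# the individual molecules of that species in the bin.
.assign_molecule_votes <- function(mol, bin_of_mol, split, profiles, seed) {
  cats <- names(split)
  n <- nrow(mol)
  votes <- integer(n)
  gene_idx <- match(mol$gene, rownames(profiles))
  key <- paste(bin_of_mol, gene_idx)
  groups <- split(seq_len(n), key)
  # per-category counts for each (bin, gene) cell
  .with_seed(seed, {
    for (grp in groups) {
      b <- bin_of_mol[grp[1]]
      g <- gene_idx[grp[1]]
      per_cat <- vapply(split, function(m) m[b, g], numeric(1))
      lab <- rep.int(seq_along(cats), round(per_cat))
      if (length(lab) < length(grp))
        lab <- c(lab, sample.int(length(cats), length(grp) - length(lab), replace = TRUE))
      votes[grp] <- lab[sample.int(length(lab))][seq_along(grp)]
    }
  })
  votes
}

#' Pool annotated molecules into segment expression profiles
#'
#' Sums gene counts and category votes per segment; segments with fewer
#' than `min_molecules` molecules are excluded.
#'
#' @param mol Molecule table with `gene`, `segment_id` and optionally
#'   `category` columns.
#' @param min_molecules Minimum molecules per retained segment (default 20).
#' @return List with `counts` (sparse segments x genes), `category` (modal
#'   category per segment, if present) and `sizes`.
#' @export
pool_segments <- function(mol, min_molecules = 20) {
  if (is.null(mol$segment_id)) stop("molecule table has no segment_id column")
  sizes <- table(mol$segment_id)
  keep_ids <- names(sizes)[sizes >= min_molecules]
  sel <- mol$segment_id %in% keep_ids
  m <- mol[sel, , drop = FALSE]
  genes <- sort(unique(mol$gene))
  segs <- sort(keep_ids)
  counts <- Matrix::sparseMatrix(
    i = match(as.character(m$segment_id), segs), j = match(m$gene, genes), x = 1,
    dims = c(length(segs), length(genes)), dimnames = list(segs, genes)
  )
  category <- NULL
  if (!is.null(m$category)) {
    category <- vapply(segs, function(s) {
      tab <- sort(table(m$category[as.character(m$segment_id) == s]), decreasing = TRUE)
      names(tab)[1]
    }, character(1))
  }
  list(counts = .as_sparse(counts), category = category,
       sizes = setNames(as.vector(sizes[segs]), segs))
}
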