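# Collective variables from atomic configurations: index-invariant distance
# matrices (IIDM), switching-function coordination counts, largest-cosine
# angles and axis-relative spatial density maps.

#' Minimum-image distance in an orthorhombic box
#'
#' Euclidean distance with each Cartesian component wrapped to the nearest
#' periodic image; plain Euclidean distance when `box` is `NULL`.
#'
#' @param a,b numeric coordinate triples (Angstrom).
#' @param box three positive edge lengths, or `NULL` for no periodicity.
#' @return Distance in Angstrom.
#' @export
min_image_distance <- function(a, b, box = NULL) {
  d <- as.numeric(b) - as.numeric(a)
  if (!is.null(box)) {
    if (any(box <= 0)) ppa_error("box edges must be > 0", "ppa_value_error")
    d <- d - box * round(d / box)
  }
  sqrt(sum(d * d))
}

# displacements from point p to the rows of X, minimum-image wrapped
mi_disp <- function(X, p, box = NULL) {
  d <- sweep(X, 2L, p)
  if (!is.null(box)) for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

mi_dist <- function(X, p, box = NULL) {
  d <- mi_disp(X, p, box)
  sqrt(rowSums(d * d))
}

resolve_atom <- function(cfg, sel, what = "atom") {
  if (is.numeric(sel)) {
    sel <- as.integer(sel)
    if (sel < 1L || sel > length(cfg$species))
      ppa_error(sprintf("%s index %d out of range", what, sel),
                "ppa_value_error")
    return(sel)
  }
  i <- which(cfg$species == sel)
  if (length(i) == 0L)
    ppa_error(sprintf("no atom of species '%s'", sel), "ppa_value_error")
  if (length(i) > 1L)
    ppa_error(sprintf(
      "species '%s' is not unique; select the %s by index", sel, what),
      "ppa_value_error")
  i
}

# order atom indices by distance, breaking exact ties by coordinates so the
# ordering never depends on the input atom indexing
order_by_distance <- function(dist, coords) {
  order(dist, coords[, 1L], coords[, 2L], coords[, 3L])
}

#' Specification of an index-invariant distance matrix
#'
#' Describes which truncated neighbourhood of an anchor ion to turn into
#' features: how many atoms of each species form the rows (sorted by species,
#' then by distance to the anchor), and how many columns each row is
#' truncated to (sorted the same way around the row atom). The production
#' setting for an ion pair in water is the counterion plus the 15 closest
#' oxygens and 30 closest hydrogens.
#'
#' @param anchor species symbol of the anchor atom; must occur exactly once
#'   in the configuration (or pass an integer atom index).
#' @param counts named integer vector, rows per species, e.g.
#'   `c(Cl = 1, O = 15, H = 30)`. Names fix the species sort order.
#' @param col_counts named integer vector of column truncations per species;
#'   defaults to `counts` (the anchor species always truncates to 1).
#' @param exclude_intramolecular_h when `TRUE` (default), hydrogens assigned
#'   to a row oxygen's own molecule (nearest-oxygen rule) are skipped in that
#'   row's hydrogen ranking, so e.g. `...O6H1` is the closest
#'   extra-molecular hydrogen.
#' @return An object of class `ppa_iidm_spec`.
#' @export
iidm_spec <- function(anchor, counts, col_counts = counts,
                      exclude_intramolecular_h = TRUE) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    ppa_error("counts must be a named vector", "ppa_value_error")
  if (any(counts < 1)) ppa_error("counts must be positive", "ppa_value_error")
  structure(list(anchor = anchor, counts = counts, col_counts = col_counts,
                 exclude_intramolecular_h = isTRUE(exclude_intramolecular_h)),
            class = "ppa_iidm_spec")
}

#' Build the index-invariant distance matrix around an anchor atom
#'
#' Rows are the anchor's neighbours, sorted first by species (in the order of
#' `spec$counts`) and then by distance to the anchor, truncated to the
#' requested counts. Within each row, columns are that atom's neighbours in
#' the truncated pool (anchor plus all row atoms), sorted by species and
#' distance to the row atom and truncated per `spec$col_counts`. Every entry
#' is named `XYiZj` -- the distance from the i-th closest Y to the anchor X
#' to that atom's j-th closest Z -- while anchor-to-row distances are named
#' `XYi`. Exact distance ties are broken by coordinates, never by input atom
#' order, so the matrix is invariant under any permutation of the input
#' indexing.
#'
#' @param cfg a [configuration()].
#' @param spec an [iidm_spec()].
#' @return An object of class `ppa_iidm`: list with the named `features`
#'   vector, `row_labels` and the anchor species.
#' @export
build_iidm <- function(cfg, spec) {
  stopifnot(inherits(cfg, "ppa_config"), inherits(spec, "ppa_iidm_spec"))
  anchor <- resolve_atom(cfg, spec$anchor, "anchor")
  Xsym <- cfg$species[anchor]
  dA <- mi_dist(cfg$coords, cfg$coords[anchor, ], cfg$box)

  row_idx <- integer(0L)
  row_label <- character(0L)
  for (s in names(spec$counts)) {
    cand <- setdiff(which(cfg$species == s), anchor)
    k <- spec$counts[[s]]
    if (length(cand) < k)
      ppa_error(sprintf(
        "insufficient atoms of species '%s': need %d, have %d",
        s, k, length(cand)), "ppa_value_error")
    cand <- cand[order_by_distance(dA[cand], cfg$coords[cand, , drop = FALSE])]
    row_idx <- c(row_idx, cand[seq_len(k)])
    row_label <- c(row_label, paste0(s, seq_len(k)))
  }

  # molecule assignment: each hydrogen belongs to its nearest oxygen
  h_owner <- rep(NA_integer_, length(cfg$species))
  if (spec$exclude_intramolecular_h) {
    os <- which(cfg$species == "O")
    hs <- which(cfg$species == "H")
    if (length(os) && length(hs))
      for (h in hs) {
        dh <- mi_dist(cfg$coords[os, , drop = FALSE], cfg$coords[h, ], cfg$box)
        h_owner[h] <- os[which.min(dh)]
      }
  }

  pool <- c(anchor, row_idx)
  pool_species <- cfg$species[pool]
  col_species <- unique(c(Xsym, names(spec$counts)))
  features <- stats::setNames(dA[row_idx], paste0(Xsym, row_label))

  for (ri in seq_along(row_idx)) {
    y <- row_idx[ri]
    dY <- mi_dist(cfg$coords[pool, , drop = FALSE], cfg$coords[y, ], cfg$box)
    for (z in col_species) {
      cand <- which(pool_species == z & pool != y)
      if (cfg$species[y] == "O" && z == "H" && spec$exclude_intramolecular_h)
        cand <- cand[h_owner[pool[cand]] != y]
      if (!length(cand)) next
      cand <- cand[order_by_distance(dY[cand],
                                     cfg$coords[pool[cand], , drop = FALSE])]
      kz <- if (z %in% names(spec$col_counts)) spec$col_counts[[z]]
            else if (z %in% names(spec$counts)) spec$counts[[z]]
            else 1L  # the anchor species: only the anchor itself is in the pool
      take <- seq_len(min(kz, length(cand)))
      features[paste0(Xsym, row_label[ri], z, take)] <- dY[cand[take]]
    }
  }
  structure(list(features = features, row_labels = row_label, anchor = Xsym),
            class = "ppa_iidm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ppa_iidm <- function(x, ...) {
  cat(sprintf("<ppa_iidm> anchor %s, %d rows, %d features\n",
              x$anchor, length(x$row_labels), length(x$features)))
  invisible(x)
}

#' Extract a single named IIDM feature
#'
#' Feature names follow the `XYi` / `XYiZj` convention of [build_iidm()]:
#' `"NaO6"` is the distance from the Na anchor to its 6th-closest oxygen,
#' `"NaO6H4"` the distance from that oxygen to its 4th-closest (by default
#' extra-molecular) hydrogen within the truncated pool.
#'
#' @param cfg a [configuration()].
#' @param spec an [iidm_spec()].
#' @param name feature name.
#' @return The distance in Angstrom.
#' @export
iidm_feature <- function(cfg, spec, name) {
  if (!grepl("^[A-Z][a-z]?[A-Z][a-z]?[0-9]+([A-Z][a-z]?[0-9]+)?$", name))
    ppa_error(sprintf("malformed IIDM feature name '%s'", name),
              "ppa_value_error")
  m <- build_iidm(cfg, spec)
  if (!name %in% names(m$features))
    ppa_error(sprintf(
      "feature '%s' not present (rank beyond truncation?)", name),
      "ppa_value_error")
  unname(m$features[name])
}

#' Smooth switching-function count of bridging atoms
#'
#' Counts atoms simultaneously inside the solvation shells of two centres by
#' summing \eqn{f(d_a)\,f(d_b)} over candidate atoms, where the logistic
#' switching function \eqn{f(d) = 1/(1 + e^{k (d - r_0)})} transitions
#' smoothly from one at short distances through one half at the solvation
#' radius \eqn{r_0} to zero far away. The result is generally fractional;
#' with the candidates taken as water oxygens around an ion pair this is the
#' bridging-water count \eqn{N_B}.
#'
#' @param cfg a [configuration()].
#' @param center_a,center_b atom selectors (unique species symbol or index).
#' @param r0 solvation radius (Angstrom).
#' @param steepness logistic steepness \eqn{k} (1/Angstrom).
#' @param species species of the counted atoms (default `"O"`).
#' @return The smooth (possibly fractional) count.
#' @export
switching_count <- function(cfg, center_a, center_b, r0, steepness,
                            species = "O") {
  if (r0 <= 0 || steepness <= 0)
    ppa_error("r0 and steepness must be positive", "ppa_value_error")
  ia <- resolve_atom(cfg, center_a, "center_a")
  ib <- resolve_atom(cfg, center_b, "center_b")
  cand <- setdiff(which(cfg$species == species), c(ia, ib))
  if (!length(cand)) return(0)
  f <- function(d) 1 / (1 + exp(steepness * (d - r0)))
  da <- mi_dist(cfg$coords[cand, , drop = FALSE], cfg$coords[ia, ], cfg$box)
  db <- mi_dist(cfg$coords[cand, , drop = FALSE], cfg$coords[ib, ], cfg$box)
  sum(f(da) * f(db))
}

#' Largest cosine of a shell angle
#'
#' Over all candidate atoms of the given species within `shell_radius` of
#' the apex atom, returns the maximum cosine of the angle at the apex formed
#' by `arm1` and the candidate. With apex Cl, arm Na and hydrogen candidates
#' this is the `cos(alpha)` parameter (angle Na-Cl-H); a candidate collinear
#' beyond the apex gives 1.
#'
#' @param cfg a [configuration()].
#' @param apex,arm1 atom selectors (unique species symbol or index).
#' @param species candidate species.
#' @param shell_radius shell membership radius around the apex (Angstrom).
#' @return Maximum cosine over the candidates.
#' @export
largest_cosine <- function(cfg, apex, arm1, species, shell_radius) {
  ia <- resolve_atom(cfg, apex, "apex")
  i1 <- resolve_atom(cfg, arm1, "arm1")
  cand <- setdiff(which(cfg$species == species), c(ia, i1))
  if (length(cand)) {
    d <- mi_dist(cfg$coords[cand, , drop = FALSE], cfg$coords[ia, ], cfg$box)
    cand <- cand[d <= shell_radius]
  }
  if (!length(cand))
    ppa_error(sprintf("no '%s' candidate within %.3g of the apex",
                      species, shell_radius), "ppa_value_error")
  v1 <- mi_disp(cfg$coords[i1, , drop = FALSE], cfg$coords[ia, ], cfg$box)[1L, ]
  v1 <- v1 / sqrt(sum(v1^2))
  vc <- mi_disp(cfg$coords[cand, , drop = FALSE], cfg$coords[ia, ], cfg$box)
  vc <- vc / sqrt(rowSums(vc^2))
  max(as.vector(vc %*% v1))
}

#' Axis-relative spatial density map
#'
#' Cylindrical histogram of selected atoms around the axis through an anchor
#' pair: the axial coordinate is the projection onto the (a -> b) axis
#' measured from atom a, the radial coordinate the distance from the axis.
#' Atoms are selected per configuration as the `ranks`-closest atoms of a
#' species to the first anchor. The histogram is normalised to a density per
#' configuration, so `sum(density * cell area)` equals the number of
#' selected atoms per frame.
#'
#' @param cfgs a list of [configuration()] objects.
#' @param anchor_pair selectors of the two axis atoms.
#' @param species selected species (default `"O"`).
#' @param ranks which closeness ranks to the first anchor to keep
#'   (default `1:15`).
#' @param n_axial,n_radial bin counts.
#' @param axial_range,radial_max histogram extents; default to the data.
#' @return An object of class `ppa_axial_map`: bin edges/mids, the `density`
#'   matrix (axial x radial) and the per-frame selection count.
#' @export
axial_density_map <- function(cfgs, anchor_pair, species = "O", ranks = 1:15,
                              n_axial = 40L, n_radial = 20L,
                              axial_range = NULL, radial_max = NULL) {
  if (inherits(cfgs, "ppa_config")) cfgs <- list(cfgs)
  if (!length(cfgs)) ppa_error("no configurations", "ppa_value_error")
  ax <- numeric(0L)
  rad <- numeric(0L)
  for (cfg in cfgs) {
    ia <- resolve_atom(cfg, anchor_pair[[1L]], "anchor a")
    ib <- resolve_atom(cfg, anchor_pair[[2L]], "anchor b")
    u <- mi_disp(cfg$coords[ib, , drop = FALSE], cfg$coords[ia, ], cfg$box)[1L, ]
    L <- sqrt(sum(u^2))
    if (L < 1e-9)
      ppa_error("degenerate axis: coincident anchor atoms", "ppa_value_error")
    u <- u / L
    cand <- setdiff(which(cfg$species == species), c(ia, ib))
    d <- mi_dist(cfg$coords[cand, , drop = FALSE], cfg$coords[ia, ], cfg$box)
    cand <- cand[order_by_distance(d, cfg$coords[cand, , drop = FALSE])]
    sel <- cand[ranks[ranks <= length(cand)]]
    disp <- mi_disp(cfg$coords[sel, , drop = FALSE], cfg$coords[ia, ], cfg$box)
    s <- as.vector(disp %*% u)
    perp <- disp - outer(s, u)
    ax <- c(ax, s)
    rad <- c(rad, sqrt(rowSums(perp^2)))
  }
  if (is.null(axial_range)) axial_range <- range(ax)
  if (is.null(radial_max)) radial_max <- max(rad)
  bx <- seq(axial_range[1L], axial_range[2L], length.out = n_axial + 1L)
  br <- seq(0, radial_max, length.out = n_radial + 1L)
  qx <- pmin(pmax(findInterval(ax, bx), 1L), n_axial)
  qr <- pmin(pmax(findInterval(rad, br), 1L), n_radial)
  counts <- matrix(0, n_axial, n_radial)
  for (k in seq_along(qx)) counts[qx[k], qr[k]] <- counts[qx[k], qr[k]] + 1
  cell <- diff(bx)[1L] * diff(br)[1L]
  structure(list(axial_breaks = bx, radial_breaks = br,
                 axial_mids = (bx[-1L] + bx[-length(bx)]) / 2,
                 radial_mids = (br[-1L] + br[-length(br)]) / 2,
                 density = counts / (length(cfgs) * cell),
                 n_per_frame = length(ax) / length(cfgs)),
            class = "ppa_axial_map")
}
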