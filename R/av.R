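# Accessible-volume (AV) modelling of a linker-tethered dye on a coarse
# pseudo-atom B-form duplex. A grid point belongs to the AV iff (a) a
# clash-free tether path of length <= linker_length and width linker_width
# connects it to the attachment atom, and (b) a dye sphere of each
# configured radius fits there without clashing. Path lengths are exact
# Euclidean distances where the straight line to the attachment is
# unobstructed, and shortest-path (Dijkstra) distances on a dense-
# neighborhood grid graph where it is not; the graph distance is an upper
# bound, so the AV it yields is (slightly) conservative.

# coarse pseudo-atom geometry (Angstrom): radial position, azimuthal offset
# from the nucleotide reference angle (degrees) and clash radius. The
# azimuthally spread backbone spheres reproduce realistic groove widths
# (vdW gaps of a few Angstrom) so that tether paths cannot thread through
# holes an all-atom surface would not have.
.nt_spheres <- function() {
  data.frame(role = c("phosphate", "phosphate", "phosphate",
                      "sugar", "sugar", "base_out", "base_in",
                      "minor_wall", "major_edge", "major_edge"),
             r_axis = c(9.2, 9.2, 9.2, 6.9, 6.9, 5.0, 2.5, 8.0, 8.5, 8.5),
             dtheta = c(-22, 0, 22, -11, 11, 0, 0, 77, -63, -143),
             radius = c(3.0, 3.0, 3.0, 2.8, 2.8, 3.0, 3.0, 4.3, 3.0, 3.0))
}

.complement <- c(A = "T", T = "A", G = "C", C = "G", X = "X")

#' Specification of a duplex / junction construct
#'
#' Describes a B-form duplex for [build_duplex_model()]: the top-strand
#' sequence, the aligned bottom-strand sequence (position i of `bottom`
#' pairs position i of `top`; derived as the complement when `NULL`),
#' structural features, and the dye attachment site. Features are lists:
#' `list(type = "gap", strand =, positions =)` removes nucleotides,
#' `list(type = "overhang", strand =, positions =)` removes the *paired*
#' strand at those positions leaving the named strand single-stranded, and
#' `list(type = "nick", strand =, after =)` records a backbone break
#' (no pseudo-atoms change).
#'
#' @param top top-strand sequence (5'->3'), characters in ACGT.
#' @param bottom aligned pairing-partner sequence, or `NULL` for the
#'   complement.
#' @param features list of feature lists, see above.
#' @param attachment list with `strand` (1 = top, 2 = bottom), `position`
#'   (bp index) and `atom` (only `"C5"`, the pyrimidine attachment of a
#'   Cy3-dT label).
#' @return A list of class `duplex_spec`.
#' @export
duplex_spec <- function(top, bottom = NULL, features = list(),
                        attachment = list(strand = 1, position = 1,
                                          atom = "C5")) {
  top_v <- strsplit(toupper(top), "")[[1]]
  if (!all(top_v %in% names(.complement)))
    stop("top sequence must use A, C, G, T")
  if (is.null(bottom)) {
    bot_v <- unname(.complement[top_v])
  } else {
    bot_v <- strsplit(toupper(bottom), "")[[1]]
    if (length(bot_v) != length(top_v))
      stop("bottom must align with top (one character per bp)")
    paired <- bot_v != "X" & top_v != "X"
    if (any(bot_v[paired] != .complement[top_v[paired]]))
      stop("paired region is not complementary")
  }
  n <- length(top_v)
  for (f in features) {
    if (!f$type %in% c("gap", "overhang", "nick"))
      stop("unknown feature type: ", f$type)
    if (f$type %in% c("gap", "overhang") && any(f$positions > n))
      stop("feature positions outside the sequence")
  }
  if (attachment$position > n || attachment$position < 1)
    stop("attachment position outside the sequence")
  att_base <- if (attachment$strand == 1) top_v[attachment$position]
              else bot_v[attachment$position]
  if (identical(attachment$atom, "C5") && !att_base %in% c("T", "C"))
    stop("C5 attachment requires a pyrimidine (T or C) at the labelled site")
  structure(list(top = top_v, bottom = bot_v, features = features,
                 attachment = attachment),
            class = "duplex_spec")
}

#' Build a coarse pseudo-atom model of a B-form duplex
#'
#' Ideal B-form geometry (rise 3.4 Angstrom/bp, twist 36 degrees/bp, helix
#' axis along z) with a coarse pseudo-atom sphere set per nucleotide:
#' azimuthally spread backbone (phosphate/sugar) spheres, two base spheres
#' and groove-wall spheres that reproduce realistic groove widths.
#' Unpaired nucleotides keep only backbone and base spheres. Gap features
#' delete the named nucleotides' spheres; overhangs leave the single
#' strand's spheres in place and delete the missing partner strand; nicks
#' change nothing sterically.
#'
#' @param spec a [duplex_spec()].
#' @param rise helical rise per bp in Angstrom (default 3.4).
#' @param twist helical twist per bp in degrees (default 36).
#' @param strand_offset azimuthal offset of the second strand in degrees
#'   (default 154, placing the minor groove between the backbones).
#' @return An object of class `helix_model`: `atoms` (data.frame x, y, z,
#'   radius, base, strand, role), `attachment` (point, base, strand),
#'   `rise`, `twist`, `n_bp`. The helix axis is the z axis.
#' @export
build_duplex_model <- function(spec, rise = 3.4, twist = 36,
                               strand_offset = 154) {
  stopifnot(inherits(spec, "duplex_spec"))
  n <- length(spec$top)
  present <- matrix(TRUE, nrow = 2, ncol = n)
  present[1, spec$top == "X"] <- FALSE
  present[2, spec$bottom == "X"] <- FALSE
  for (f in spec$features) {
    if (f$type == "gap") present[f$strand, f$positions] <- FALSE
    if (f$type == "overhang") present[3 - f$strand, f$positions] <- FALSE
  }
  sph <- .nt_spheres()
  rows <- list()
  for (j in seq_len(n)) {
    z <- (j - 1) * rise
    for (s in 1:2) {
      if (!present[s, j]) next
      # unpaired (single-stranded) nucleotides have no groove geometry:
      # only their backbone and base spheres remain
      sp_j <- if (present[3 - s, j]) sph
              else sph[sph$role %in% c("phosphate", "sugar", "base_out"), ]
      theta <- ((j - 1) * twist + sp_j$dtheta +
                  if (s == 2) strand_offset else 0) * pi / 180
      rows[[length(rows) + 1L]] <- data.frame(
        x = sp_j$r_axis * cos(theta), y = sp_j$r_axis * sin(theta), z = z,
        radius = sp_j$radius, base = j, strand = s, role = sp_j$role)
    }
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  att <- spec$attachment
  if (!present[att$strand, att$position])
    stop("attachment nucleotide was deleted by a feature")
  th <- ((att$position - 1) * twist +
           if (att$strand == 2) strand_offset else 0) * pi / 180
  att_point <- c(5.5 * cos(th), 5.5 * sin(th), (att$position - 1) * rise)
  structure(list(atoms = atoms, attachment = list(point = att_point,
                                                  base = att$position,
                                                  strand = att$strand),
                 rise = rise, twist = twist, n_bp = n, spec = spec),
            class = "helix_model")
}

#' Junction hairpin construct with the dye offset from the junction
#'
#' Convenience [duplex_spec()] for the T-series constructs: a duplex whose
#' bottom strand ends at `junction` (the top strand continues as a
#' single-stranded overhang), with the dye attached to the bottom strand
#' `offset` bases back from the junction. T0 has the dye at the junction
#' terminal base pair, T2 two bases away, T4 four bases away.
#'
#' @param offset bases between the dye and the junction (0, 2, 4, ...).
#' @param n_bp total length of the top strand (default 16).
#' @param junction last paired position (default 10).
#' @return A list with `spec` (the [duplex_spec()]) and `junction_base`
#'   (the first overhang base, where a stacking dye would sit).
#' @export
tn_junction_spec <- function(offset, n_bp = 16, junction = 10) {
  if (offset >= junction) stop("offset must be smaller than the junction position")
  top <- paste(rep("A", n_bp), collapse = "")
  spec <- duplex_spec(top,
                      features = list(list(type = "overhang", strand = 1,
                                           positions = (junction + 1):n_bp)),
                      attachment = list(strand = 2,
                                        position = junction - offset,
                                        atom = "C5"))
  list(spec = spec, junction_base = junction + 1L)
}

#' @export
print.helix_model <- function(x, ...) {
  cat(sprintf("B-form helix model: %d bp, %d pseudo-atoms, dye on strand %d position %d\n",
              x$n_bp, nrow(x$atoms), x$attachment$strand, x$attachment$base))
  invisible(x)
}

# primitive half-space offsets within a 5x5x5 neighborhood (49 directions)
.grid_offsets <- function() {
  off <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  gcd2 <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  prim <- apply(abs(off), 1, function(v) Reduce(gcd2, v[v > 0]) == 1)
  off <- off[prim, , drop = FALSE]
  off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
        (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), , drop = FALSE]
}

# squared distance of grid points (3 coordinate vectors) to one center
.blocked_by <- function(px, py, pz, atoms, clearance) {
  blocked <- rep(FALSE, length(px))
  for (i in seq_len(nrow(atoms))) {
    rr <- (atoms$radius[i] + clearance)^2
    blocked <- blocked | ((px - atoms$x[i])^2 + (py - atoms$y[i])^2 +
                            (pz - atoms$z[i])^2 < rr)
  }
  blocked
}

#' Compute the accessible volume of a tethered dye
#'
#' Grid search over a cube of half-width `linker_length` around the
#' attachment atom. A point is accessible iff a clash-free tether path of
#' length at most `linker_length` (width `linker_width`) connects it to the
#' attachment, and a dye sphere of every radius in `dye_radii` fits without
#' clashing with any pseudo-atom. The attachment nucleotide's own spheres do
#' not obstruct the tether path (the dye is bonded there). Path lengths are
#' Euclidean wherever the straight line from the attachment is clash-free
#' and grid-geodesic (Dijkstra over a 5x5x5 neighborhood) elsewhere.
#'
#' @param model a `helix_model`, or `NULL` for free space.
#' @param params a [linker_dye_params()].
#' @param attachment attachment point override (length-3 vector, Angstrom);
#'   defaults to the model's attachment atom. Required when `model` is
#'   `NULL`.
#' @return An object of class `accessible_volume`: `points` (n x 3 matrix of
#'   allowed grid points), `volume` (Angstrom^3), `grid_spacing`,
#'   `attachment`, `mean_position`, `params`.
#' @export
compute_av <- function(model, params, attachment = NULL) {
  stopifnot(inherits(params, "linker_dye_params"))
  if (is.null(attachment)) {
    if (is.null(model)) stop("attachment must be given when model is NULL")
    attachment <- model$attachment$point
  }
  L <- params$linker_length
  h <- params$grid_spacing
  ax <- seq(-(L + 2 * h), L + 2 * h, by = h)
  nax <- length(ax)
  px <- rep(ax, times = nax * nax) + attachment[1]
  py <- rep(rep(ax, each = nax), times = nax) + attachment[2]
  pz <- rep(ax, each = nax * nax) + attachment[3]

  atoms <- if (is.null(model)) NULL else model$atoms
  if (!is.null(atoms) && !is.null(model$attachment$base)) {
    # the tether is bonded at the attachment nucleotide and exits through
    # the adjacent groove mouth: its own spheres and nearby groove walls
    # do not obstruct the path (they still obstruct the dye sphere)
    own <- atoms$base == model$attachment$base &
      atoms$strand == model$attachment$strand
    d_att <- sqrt((atoms$x - attachment[1])^2 + (atoms$y - attachment[2])^2 +
                    (atoms$z - attachment[3])^2)
    path_atoms <- atoms[!(own | d_att < 6.5), , drop = FALSE]
  } else path_atoms <- atoms

  n_pts <- length(px)
  if (is.null(atoms) || nrow(atoms) == 0) {
    path_free <- rep(TRUE, n_pts)
    dye_free <- rep(TRUE, n_pts)
  } else {
    path_free <- !.blocked_by(px, py, pz, path_atoms, params$linker_width / 2)
    dye_free <- !.blocked_by(px, py, pz, atoms, max(params$dye_radii))
  }

  d_euc <- sqrt((px - attachment[1])^2 + (py - attachment[2])^2 +
                  (pz - attachment[3])^2)
  cand <- d_euc <= L

  if (is.null(path_atoms) || nrow(path_atoms) == 0) {
    dist <- ifelse(path_free, d_euc, Inf)
  } else {
    # start point: nearest path-free grid point to the attachment (the
    # first position the tether can occupy outside the steric surface);
    # the distance from the attachment to it is charged to the tether
    near <- which(path_free & d_euc <= 6)
    if (!length(near)) stop("attachment is fully buried: empty AV")
    src <- near[which.min(d_euc[near])]
    start <- c(px[src], py[src], pz[src])
    d0 <- d_euc[src]
    d_start <- sqrt((px - start[1])^2 + (py - start[2])^2 +
                      (pz - start[3])^2)

    # line-of-sight pass: straight tether where unobstructed
    los <- .line_of_sight(px, py, pz, cand & path_free, start,
                          path_atoms, params$linker_width / 2)
    dist <- rep(Inf, n_pts)
    dist[los] <- d0 + d_start[los]

    # Dijkstra for the shadowed remainder
    need <- cand & path_free & !los
    if (any(need)) {
      dgrid <- .grid_dijkstra(nax, h, keep = path_free & d_euc <= L + h,
                              src = src)
      dist[need] <- pmin(dist[need], d0 + dgrid[need])
    }
  }
  allowed <- path_free & dye_free & dist <= L
  pts <- cbind(x = px[allowed], y = py[allowed], z = pz[allowed])
  if (!nrow(pts)) stop("empty accessible volume")
  structure(list(points = pts, n_points = nrow(pts),
                 volume = nrow(pts) * h^3, grid_spacing = h,
                 attachment = attachment, mean_position = colMeans(pts),
                 params = params),
            class = "accessible_volume")
}

# Straight-segment visibility from the attachment: exact segment-sphere
# intersection against the obstacle spheres dilated by the path clearance.
.line_of_sight <- function(px, py, pz, cand, att, atoms, clearance) {
  los <- cand
  idx <- which(cand)
  if (!length(idx)) return(los)
  qx <- px[idx] - att[1]; qy <- py[idx] - att[2]; qz <- pz[idx] - att[3]
  seg2 <- pmax(qx^2 + qy^2 + qz^2, 1e-12)
  ok <- rep(TRUE, length(idx))
  for (i in seq_len(nrow(atoms))) {
    cx <- atoms$x[i] - att[1]; cy <- atoms$y[i] - att[2]
    cz <- atoms$z[i] - att[3]
    tt <- pmin(pmax((qx * cx + qy * cy + qz * cz) / seg2, 0), 1)
    d2 <- (tt * qx - cx)^2 + (tt * qy - cy)^2 + (tt * qz - cz)^2
    ok <- ok & d2 >= (atoms$radius[i] + clearance)^2
  }
  los[idx] <- ok
  los
}

# Single-source shortest paths on the masked grid (49-direction
# neighborhood, Euclidean edge weights). Returns distances for all points
# (Inf where unreachable or masked out).
.grid_dijkstra <- function(nax, h, keep, src) {
  offs <- .grid_offsets()
  lin <- function(i, j, k) (k - 1L) * nax * nax + (j - 1L) * nax + i
  fl <- vector("list", nrow(offs))
  tl <- vector("list", nrow(offs))
  wl <- numeric(nrow(offs))
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    ir <- max(1, 1 - d[1]):min(nax, nax - d[1])
    jr <- max(1, 1 - d[2]):min(nax, nax - d[2])
    kr <- max(1, 1 - d[3]):min(nax, nax - d[3])
    I <- rep(ir, times = length(jr) * length(kr))
    J <- rep(rep(jr, each = length(ir)), times = length(kr))
    K <- rep(kr, each = length(ir) * length(jr))
    a <- lin(I, J, K); b <- lin(I + d[1], J + d[2], K + d[3])
    sel <- keep[a] & keep[b]
    fl[[r]] <- a[sel]; tl[[r]] <- b[sel]
    wl[r] <- sqrt(sum(d^2)) * h
  }
  from <- unlist(fl); to <- unlist(tl)
  w <- rep(wl, lengths(fl))
  g <- igraph::make_graph(rbind(from, to), n = nax^3, directed = FALSE)
  as.numeric(igraph::distances(g, v = src, weights = w, mode = "out"))
}

#' @export
print.accessible_volume <- function(x, ...) {
  cat(sprintf("accessible volume: %d grid points (%.1f Angstrom^3) at %.2f Angstrom spacing\n",
              x$n_points, x$volume, x$grid_spacing))
  cat(sprintf("  mean dye position: (%.1f, %.1f, %.1f)\n",
              x$mean_position[1], x$mean_position[2], x$mean_position[3]))
  invisible(x)
}

#' @export
plot.accessible_volume <- function(x, ...) {
  graphics::plot(x$points[, "x"], x$points[, "z"], pch = ".",
                 xlab = "x (Angstrom)", ylab = "z (Angstrom)",
                 asp = 1, ...)
  graphics::points(x$attachment[1], x$attachment[3], col = 2, pch = 19)
  invisible(x)
}

#' Axial reach of the accessible volume
#'
#' Maximum displacement of allowed dye positions along the helix axis,
#' measured from the attachment nucleotide's base-pair center, expressed in
#' bases (divided by the rise, rounded up).
#'
#' @param av an `accessible_volume`.
#' @param model the `helix_model` it was computed on, or `NULL` (free
#'   space: measured from the attachment point, default rise).
#' @return integer number of bases.
#' @export
axial_reach <- function(av, model = NULL) {
  stopifnot(inherits(av, "accessible_volume"))
  rise <- if (is.null(model)) 3.4 else model$rise
  z0 <- if (is.null(model)) av$attachment[3]
        else (model$attachment$base - 1) * model$rise
  ceiling(max(abs(av$points[, "z"] - z0)) / rise)
}

#' Fraction of the accessible volume in the stacking shell
#'
#' Fraction of allowed dye positions within `shell` Angstrom of the surface
#' of the junction terminal base's pseudo-atom: a geometric proxy for how
#' easily the dye can stack at the junction.
#'
#' @param av an `accessible_volume`.
#' @param model the `helix_model`.
#' @param junction_base base-pair index of the junction terminal base.
#' @param strand strand carrying that base (default 1).
#' @param shell shell thickness beyond the clash radius, Angstrom
#'   (default 5).
#' @return fraction in [0, 1].
#' @export
stacking_fraction <- function(av, model, junction_base, strand = 1,
                              shell = 5) {
  stopifnot(inherits(av, "accessible_volume"),
            inherits(model, "helix_model"))
  a <- model$atoms
  hit <- a$base == junction_base & a$strand == strand & a$role == "base_out"
  if (!any(hit)) stop("no base pseudo-atom at junction index ",
                      junction_base, " on strand ", strand)
  ctr <- a[which(hit)[1], c("x", "y", "z")]
  rad <- a$radius[which(hit)[1]]
  d <- sqrt((av$points[, "x"] - ctr$x)^2 + (av$points[, "y"] - ctr$y)^2 +
              (av$points[, "z"] - ctr$z)^2)
  mean(d <= rad + shell)
}

#' Write an AV cloud (and helix model) as a PDB file
#'
#' One HETATM pseudo-atom per allowed grid point (subsampled to at most
#' 9999 points, chain B), preceded by the helix pseudo-atoms (chain A), for
#' inspection in any molecular viewer.
#'
#' @param av an `accessible_volume`.
#' @param path output file path.
#' @param model optional `helix_model` written as chain A.
#' @return the path, invisibly.
#' @export
write_av_cloud <- function(av, path, model = NULL) {
  stopifnot(inherits(av, "accessible_volume"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write AV cloud to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  fmt <- "HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  serial <- 0L
  if (!is.null(model)) {
    for (i in seq_len(nrow(model$atoms))) {
      serial <- serial + 1L
      writeLines(sprintf(fmt, serial, " C", "DNA", "A", model$atoms$base[i],
                         model$atoms$x[i], model$atoms$y[i],
                         model$atoms$z[i], 1, 0, "C"), con)
    }
  }
  pts <- av$points
  if (nrow(pts) > 9999L)
    pts <- pts[round(seq(1, nrow(pts), length.out = 9999L)), , drop = FALSE]
  for (i in seq_len(nrow(pts))) {
    serial <- serial + 1L
    writeLines(sprintf(fmt, serial, " C", "AV", "B", 1L,
                       pts[i, 1], pts[i, 2], pts[i, 3], 1, 0, "C"), con)
  }
  writeLines("END", con)
  invisible(path)
}
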