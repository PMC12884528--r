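# Nanostructure geometries: atomistic substrate containers, Mackay icosahedral
# clusters, graphene disks, neighbor graphs, XYZ input/output.
# Positions are stored in Angstrom; converters in units.R are the only place
# units change.

#' Atomistic nanostructure
#'
#' Container for the plasmonic substrate: atomic positions, element/material
#' labels, an optional nearest-neighbor graph, and the key of the material
#' parameter set governing its response.
#'
#' @param positions numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param labels character vector of length N with element tags.
#' @param material_id key naming the material (e.g. `"gold"`, `"graphene"`).
#' @param neighbor_pairs optional data.frame with integer columns `i`, `j` and
#'   numeric `r` (Angstrom); must contain both `(i, j)` and `(j, i)`.
#' @param validate check invariants (no overlapping atoms, symmetric neighbor
#'   relation, stored pair distances consistent with positions).
#' @return an object of class `nanostructure`.
#' @seealso [build_mackay_icosahedron()], [build_graphene_disk()],
#'   [neighbor_graph()], [read_xyz()]
#' @export
nanostructure <- function(positions, labels = NULL, material_id = "gold",
                          neighbor_pairs = NULL, validate = TRUE) {
  positions <- as.matrix(positions)
  if (length(positions) == 0L) {
    positions <- matrix(numeric(0), 0L, 3L)
  }
  if (ncol(positions) != 3L || !is.numeric(positions)) {
    stop("`positions` must be a numeric N x 3 matrix")
  }
  n <- nrow(positions)
  if (is.null(labels)) labels <- rep("X", n)
  if (length(labels) != n) stop("`labels` must have one entry per atom")
  dimnames(positions) <- NULL
  obj <- structure(
    list(positions = positions, labels = as.character(labels),
         material_id = material_id, neighbor_pairs = neighbor_pairs),
    class = "nanostructure")
  if (validate) validate_nanostructure(obj)
  obj
}

#' @rdname nanostructure
#' @param x a `nanostructure`.
#' @export
validate_nanostructure <- function(x) {
  stopifnot(inherits(x, "nanostructure"))
  n <- nrow(x$positions)
  if (n > 1L) {
    close_pairs <- .pair_list(x$positions, cutoff = 0.5)
    if (nrow(close_pairs) > 0L) {
      stop(sprintf("overlapping atoms: pair (%d, %d) at %.4f Angstrom < 0.5",
                   close_pairs$i[1], close_pairs$j[1], close_pairs$r[1]))
    }
  }
  np <- x$neighbor_pairs
  if (!is.null(np) && nrow(np) > 0L) {
    if (!all(c("i", "j", "r") %in% names(np))) {
      stop("neighbor_pairs must have columns i, j, r")
    }
    key <- paste(np$i, np$j)
    rev_key <- paste(np$j, np$i)
    if (!all(rev_key %in% key)) stop("neighbor relation is not symmetric")
    if (any(np$i == np$j)) stop("neighbor relation contains self pairs")
    d <- sqrt(rowSums((x$positions[np$i, , drop = FALSE] -
                         x$positions[np$j, , drop = FALSE])^2))
    if (any(abs(d - np$r) > 1e-10)) {
      stop("stored pair distances disagree with positions beyond 1e-10 Angstrom")
    }
  }
  invisible(x)
}

#' @export
print.nanostructure <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("<nanostructure> %d atoms, material '%s'\n", n, x$material_id))
  if (n > 0L) {
    ext <- apply(x$positions, 2L, function(p) diff(range(p)))
    cat(sprintf("  extent (Angstrom): %.2f x %.2f x %.2f\n",
                ext[1], ext[2], ext[3]))
  }
  if (!is.null(x$neighbor_pairs)) {
    cat(sprintf("  neighbor graph: %d directed pairs\n", nrow(x$neighbor_pairs)))
  } else {
    cat("  neighbor graph: not built\n")
  }
  invisible(x)
}

# All pairs with distance <= cutoff (i < j), via a cell list so that large
# structures stay O(N).  Returns data.frame(i, j, r) in Angstrom.
.pair_list <- function(pos, cutoff) {
  n <- nrow(pos)
  empty <- data.frame(i = integer(0), j = integer(0), r = numeric(0))
  if (n < 2L) return(empty)
  if (n <= 2500L) {
    d <- as.matrix(stats::dist(pos))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(empty)
    return(data.frame(i = idx[, 1L], j = idx[, 2L],
                      r = d[idx]))
  }
  cell <- floor(sweep(pos, 2L, apply(pos, 2L, min)) / cutoff)
  span <- apply(cell, 2L, max) + 3
  enc <- function(cm) (cm[, 1L] + 1) + span[1] * ((cm[, 2L] + 1) +
                        span[2] * (cm[, 3L] + 1))
  key <- enc(cell)
  ukey <- unique(key)
  id <- match(key, ukey)
  bl <- split(seq_len(n), id)               # bucket id -> atom indices
  sizes <- lengths(bl)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  # self cell plus half of the offsets, so each unordered pair appears once
  offsets <- offsets[offsets[, 1] > 0 |
                       (offsets[, 1] == 0 & offsets[, 2] > 0) |
                       (offsets[, 1] == 0 & offsets[, 2] == 0 &
                          offsets[, 3] >= 0), , drop = FALSE]
  acc_i <- list(); acc_j <- list(); acc_r <- list()
  for (k in seq_len(nrow(offsets))) {
    off <- offsets[k, ]
    if (all(off == 0)) {
      multi <- which(sizes >= 2L)
      if (length(multi) == 0L) next
      prs <- lapply(bl[multi], function(b) {
        m <- length(b)
        ia <- rep(b, times = m); jb <- rep(b, each = m)
        cbind(ia[ia < jb], jb[ia < jb])
      })
      prs <- do.call(rbind, prs)
      ia <- prs[, 1L]; jb <- prs[, 2L]
    } else {
      tkey <- enc(sweep(cell, 2L, -off))
      tid <- match(tkey, ukey)
      valid <- which(!is.na(tid))
      if (length(valid) == 0L) next
      ia <- rep(valid, times = sizes[tid[valid]])
      jb <- unlist(bl[tid[valid]], use.names = FALSE)
    }
    dv <- pos[ia, , drop = FALSE] - pos[jb, , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    sel <- which(r <= cutoff)
    if (length(sel) == 0L) next
    acc_i[[length(acc_i) + 1L]] <- ia[sel]
    acc_j[[length(acc_j) + 1L]] <- jb[sel]
    acc_r[[length(acc_r) + 1L]] <- r[sel]
  }
  if (length(acc_i) == 0L) return(empty)
  i <- unlist(acc_i, use.names = FALSE)
  j <- unlist(acc_j, use.names = FALSE)
  r <- unlist(acc_r, use.names = FALSE)
  data.frame(i = pmin(i, j), j = pmax(i, j), r = r)
}

#' Closed-shell Mackay icosahedral cluster
#'
#' Builds the fcc-twinned (Mackay) icosahedron with `shells` complete shells
#' around a central atom.  The cluster is the union of 20 fcc tetrahedra
#' spanned by the origin and triples of adjacent icosahedron vertices; the
#' atom count is the icosahedral magic number `(10k^3 + 15k^2 + 11k + 3)/3`.
#' Nearest-neighbor distances within a shell equal `nn_distance`; radial
#' (inter-shell) bonds are contracted by the icosahedral factor sin(2*pi/5) ~
#' 0.951, as in the Mackay construction.
#'
#' @param shells non-negative integer number of closed shells (0 = single atom).
#' @param nn_distance intra-shell nearest-neighbor distance (Angstrom); the
#'   default 2.885 is the gold bulk value.
#' @param label element tag for all atoms.
#' @param material_id material key, defaults to `"gold"`.
#' @return a [nanostructure()] centred at the origin.
#' @examples
#' nrow(build_mackay_icosahedron(1)$positions)   # 13
#' @export
build_mackay_icosahedron <- function(shells, nn_distance = 2.885,
                                     label = "Au", material_id = "gold") {
  if (length(shells) != 1L || is.na(shells) || shells < 0 ||
      shells != round(shells)) {
    stop("`shells` must be a single non-negative integer")
  }
  if (nn_distance <= 0) stop("`nn_distance` must be positive")
  shells <- as.integer(shells)
  if (shells == 0L) {
    return(nanostructure(matrix(0, 1L, 3L), label, material_id))
  }
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c( 1,  phi, 0), c(-1,  phi, 0), c( 1, -phi, 0), c(-1, -phi, 0),
    c( phi, 0,  1), c( phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1))
  v <- v * (nn_distance / 2)          # edge length = nn_distance
  edge <- nn_distance
  # 20 faces: triples of mutually adjacent vertices
  dmat <- as.matrix(stats::dist(v))
  adj <- abs(dmat - edge) < 1e-9 * edge
  faces <- list()
  for (a in 1:10) for (b in (a + 1):11) for (cc in (b + 1):12) {
    if (adj[a, b] && adj[b, cc] && adj[a, cc]) faces[[length(faces) + 1L]] <- c(a, b, cc)
  }
  k <- shells
  abc <- expand.grid(a = 0:k, b = 0:k, c = 0:k)
  abc <- abc[abc$a + abc$b + abc$c <= k, , drop = FALSE]
  pts <- vector("list", length(faces))
  for (f in seq_along(faces)) {
    w <- v[faces[[f]], , drop = FALSE]
    pts[[f]] <- as.matrix(abc) %*% w
  }
  pts <- do.call(rbind, pts)
  key <- paste(round(pts[, 1] / (1e-6 * nn_distance)),
               round(pts[, 2] / (1e-6 * nn_distance)),
               round(pts[, 3] / (1e-6 * nn_distance)))
  pts <- pts[!duplicated(key), , drop = FALSE]
  nanostructure(pts, rep(label, nrow(pts)), material_id)
}

#' Magic number of the Mackay icosahedron
#'
#' Atom count of the closed-shell icosahedral cluster with `k` shells.
#'
#' @param k non-negative integer shell count (vectorized).
#' @return integer atom counts `(10k^3 + 15k^2 + 11k + 3)/3`.
#' @export
icosahedron_magic_number <- function(k) {
  if (any(k < 0) || any(k != round(k))) stop("`k` must be non-negative integers")
  as.integer(round((10 * k^3 + 15 * k^2 + 11 * k + 3) / 3))
}

#' Graphene disk
#'
#' Cuts a disk out of the infinite pristine honeycomb lattice: the disk center
#' is placed at a hexagon center and every atom whose distance from it is at
#' most `diameter/2` is kept.  The disk lies in the z = 0 plane.
#'
#' @param diameter disk diameter in nm.
#' @param cc_bond carbon-carbon bond length (Angstrom), default 1.42.
#' @param material_id material key, defaults to `"graphene"`.
#' @return a [nanostructure()] of carbon atoms.
#' @examples
#' gd <- build_graphene_disk(5)        # ~750 atoms
#' @export
build_graphene_disk <- function(diameter, cc_bond = 1.42,
                                material_id = "graphene") {
  if (diameter * 10 <= 2 * cc_bond) {
    stop("`diameter` too small: must exceed 2*cc_bond")
  }
  c0 <- cc_bond
  radius <- diameter * 10 / 2          # nm -> Angstrom
  a1 <- c(sqrt(3) * c0, 0)
  a2 <- c(sqrt(3) * c0 / 2, 1.5 * c0)
  basis <- rbind(c(0, 0), c(0, c0))
  hex_center <- c(sqrt(3) * c0 / 2, c0 / 2)
  nmax <- ceiling((radius + 3 * c0) / 1.5 / c0) + 1L
  mmax <- ceiling((radius + 3 * c0) / (sqrt(3) * c0)) + nmax
  grid <- expand.grid(m = -mmax:mmax, n = -nmax:nmax)
  lat <- cbind(grid$m * a1[1] + grid$n * a2[1],
               grid$m * a1[2] + grid$n * a2[2])
  pos <- rbind(sweep(lat, 2L, -basis[1, ]), sweep(lat, 2L, -basis[2, ]))
  pos <- sweep(pos, 2L, hex_center)
  keep <- pos[, 1]^2 + pos[, 2]^2 <= radius^2
  pos <- pos[keep, , drop = FALSE]
  pos3 <- cbind(pos, 0)
  nanostructure(pos3, rep("C", nrow(pos3)), material_id)
}

#' Nearest-neighbor graph
#'
#' Populates the symmetric neighbor relation of a structure with every pair of
#' atoms at distance `<= cutoff` (self pairs excluded).  The neighbor graph
#' carries the Drude conduction of the fluctuating-charge model, which is
#' restricted to nearest neighbors.
#'
#' @param structure a [nanostructure()].
#' @param cutoff pair cutoff in Angstrom; a common choice is 1.2 x the
#'   nearest-neighbor distance.
#' @return the structure with `neighbor_pairs` populated (both directions).
#' @export
neighbor_graph <- function(structure, cutoff) {
  stopifnot(inherits(structure, "nanostructure"))
  if (cutoff <= 0) stop("`cutoff` must be positive")
  half <- .pair_list(structure$positions, cutoff)
  structure$neighbor_pairs <- data.frame(
    i = c(half$i, half$j), j = c(half$j, half$i), r = c(half$r, half$r))
  validate_nanostructure(structure)
  structure
}

#' Read and write XYZ files
#'
#' Standard XYZ format: an atom-count line, a comment line, then one
#' `element x y z` record per atom in Angstrom.
#'
#' @param path file path.
#' @param material_id material key attached to the structure on read.
#' @return `read_xyz()` returns a [nanostructure()]; `write_xyz()` returns the
#'   path invisibly.
#' @export
read_xyz <- function(path, material_id = "gold") {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("XYZ parse error at line 1: file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 0L) stop("XYZ parse error at line 1: malformed atom count")
  if (length(lines) < n + 2L) {
    stop(sprintf("XYZ parse error at line %d: expected %d atom records, found %d",
                 length(lines) + 1L, n, length(lines) - 2L))
  }
  rec <- lines[seq_len(n) + 2L]
  toks <- strsplit(trimws(rec), "[[:space:]]+")
  pos <- matrix(NA_real_, n, 3L)
  lab <- character(n)
  for (ii in seq_len(n)) {
    tk <- toks[[ii]]
    if (length(tk) < 4L) {
      stop(sprintf("XYZ parse error at line %d: expected 'element x y z'", ii + 2L))
    }
    xyz <- suppressWarnings(as.numeric(tk[2:4]))
    if (any(is.na(xyz))) {
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinates", ii + 2L))
    }
    lab[ii] <- tk[1L]
    pos[ii, ] <- xyz
  }
  nanostructure(pos, lab, material_id)
}

#' @rdname read_xyz
#' @param structure a [nanostructure()].
#' @param comment comment line written to the file.
#' @export
write_xyz <- function(structure, path, comment = "written by plasmovib") {
  stopifnot(inherits(structure, "nanostructure"))
  n <- nrow(structure$positions)
  rec <- sprintf("%-4s %18.10f %18.10f %18.10f", structure$labels,
                 structure$positions[, 1], structure$positions[, 2],
                 structure$positions[, 3])
  writeLines(c(as.character(n), comment, rec), path)
  invisible(path)
}
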