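#' Sphere tessellation by icosahedron subdivision
#'
#' Builds a near-uniform tessellation of the unit sphere by recursively
#' subdividing the faces of a regular icosahedron, and reduces it to a
#' hemisphere representation (one representative per antipodal vertex pair)
#' suitable for antipodally symmetric functions such as fODFs. Vertex
#' adjacency is taken from the triangulation edges and mapped through the
#' antipodal identification, so local-maximum searches on the hemisphere see
#' neighbors across the equator.
#'
#' @param subdiv Number of subdivision rounds. Level `s` yields
#'   `10 * 4^s + 2` full-sphere vertices (level 3: 642, level 4: 2562; i.e.
#'   321 and 1281 hemisphere directions).
#' @return An object of class `sphere_tess`: a list with `dirs` (n x 3 unit
#'   vectors, hemisphere representatives), `adj` (list of integer neighbor
#'   vectors, antipodally wrapped), and `subdiv`.
#' @examples
#' tess <- sphere_tessellation(2)
#' nrow(tess$dirs)
#' @export
sphere_tessellation <- function(subdiv = 4) {
  stopifnot(subdiv >= 0, subdiv <= 6)
  t <- (1 + sqrt(5)) / 2
  verts <- matrix(c(
    -1,  t,  0,   1,  t,  0,  -1, -t,  0,   1, -t,  0,
     0, -1,  t,   0,  1,  t,   0, -1, -t,   0,  1, -t,
     t,  0, -1,   t,  0,  1,  -t,  0, -1,  -t,  0,  1
  ), ncol = 3, byrow = TRUE)
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- matrix(c(
    1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2
  ), ncol = 3, byrow = TRUE)

  for (s in seq_len(subdiv)) {
    cache <- new.env(hash = TRUE, parent = emptyenv())
    vlist <- asplit(verts, 1)
    midpoint <- function(i, j) {
      key <- if (i < j) paste(i, j) else paste(j, i)
      idx <- cache[[key]]
      if (is.null(idx)) {
        v <- verts[i, ] + verts[j, ]
        v <- v / sqrt(sum(v^2))
        vlist[[length(vlist) + 1]] <<- v
        idx <- length(vlist)
        cache[[key]] <- idx
      }
      idx
    }
    new_faces <- matrix(0L, nrow(faces) * 4L, 3L)
    for (f in seq_len(nrow(faces))) {
      a <- faces[f, 1]; b <- faces[f, 2]; c <- faces[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      new_faces[(f - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    verts <- do.call(rbind, vlist)
    verts <- verts / sqrt(rowSums(verts^2))
    faces <- new_faces
  }

  # antipodal pairing: the icosahedron is centrally symmetric and midpoint
  # subdivision preserves that, so -v is always present in the vertex set
  key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6), round(m[, 3], 6))
  anti <- match(key(-verts), key(verts))
  stopifnot(!anyNA(anti))

  tol <- 1e-9
  up <- verts[, 3] > tol |
    (abs(verts[, 3]) <= tol & (verts[, 2] > tol |
      (abs(verts[, 2]) <= tol & verts[, 1] > 0)))
  hemi_idx <- which(up)
  rep_full <- ifelse(up, match(seq_len(nrow(verts)), hemi_idx),
                     match(anti, hemi_idx))
  stopifnot(!anyNA(rep_full))

  edges <- unique(rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)]))
  ra <- rep_full[edges[, 1]]; rb <- rep_full[edges[, 2]]
  keep <- ra != rb
  ra <- ra[keep]; rb <- rb[keep]
  n <- length(hemi_idx)
  adj <- vector("list", n)
  pairs <- unique(rbind(cbind(ra, rb), cbind(rb, ra)))
  sp <- split(pairs[, 2], pairs[, 1])
  adj[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))

  structure(list(dirs = verts[hemi_idx, , drop = FALSE], adj = adj,
                 subdiv = subdiv),
            class = "sphere_tess")
}

#' @export
print.sphere_tess <- function(x, ...) {
  cat(sprintf("<sphere_tess> %d hemisphere directions (subdiv %d)\n",
              nrow(x$dirs), x$subdiv))
  invisible(x)
}

#' Full-sphere direction set of a hemisphere tessellation
#'
#' Returns the hemisphere representatives together with their antipodes,
#' giving a near-uniform full-sphere point set usable for quadrature with
#' equal weights `4 * pi / n`.
#'
#' @param tess A [sphere_tessellation()] object.
#' @return A `2n x 3` matrix of unit vectors.
#' @export
full_directions <- function(tess) {
  stopifnot(inherits(tess, "sphere_tess"))
  rbind(tess$dirs, -tess$dirs)
}

# per-session cache so repeated calls (peak extraction, CSD) reuse the
# subdivision work
.tess_cache <- new.env(parent = emptyenv())

#' Default tessellations for peak finding and CSD constraints
#'
#' `peak_tessellation()` returns the dense evaluation tessellation used for
#' fODF peak extraction (1281 hemisphere directions); `constraint_tessellation()`
#' the coarser set used for the CSD nonnegativity constraint (321 directions).
#' Both are cached per session.
#'
#' @return A [sphere_tessellation()] object.
#' @export
peak_tessellation <- function() {
  if (is.null(.tess_cache$peak)) .tess_cache$peak <- sphere_tessellation(4)
  .tess_cache$peak
}

#' @rdname peak_tessellation
#' @export
constraint_tessellation <- function() {
  if (is.null(.tess_cache$constraint))
    .tess_cache$constraint <- sphere_tessellation(3)
  .tess_cache$constraint
}
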