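# Bone shape correspondence and statistical shape modelling -------------------

# Closest points on a set of triangles to a single point p.
# tri: list of three V x 3 matrices (a, b, c) restricted to candidate rows.
# Returns list(d2 = squared distances, q = closest points). Vectorised
# implementation of the standard Voronoi-region point-triangle projection.
closest_on_triangles <- function(p, a, b, c3) {
  ab <- b - a; ac <- c3 - a
  ap <- sweep(-a, 2, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  q <- a  # default: vertex a region
  done <- d1 <= 0 & d2 <= 0
  bp <- sweep(-b, 2, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  selb <- !done & d3 >= 0 & d4 <= d3
  q[selb, ] <- b[selb, , drop = FALSE]
  done <- done | selb
  vc <- d1 * d4 - d3 * d2
  sel <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(sel)) {
    v <- d1[sel] / (d1[sel] - d3[sel])
    q[sel, ] <- a[sel, , drop = FALSE] + v * ab[sel, , drop = FALSE]
    done <- done | sel
  }
  cp <- sweep(-c3, 2, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  selc <- !done & d6 >= 0 & d5 <= d6
  q[selc, ] <- c3[selc, , drop = FALSE]
  done <- done | selc
  vb <- d5 * d2 - d1 * d6
  sel <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(sel)) {
    w <- d2[sel] / (d2[sel] - d6[sel])
    q[sel, ] <- a[sel, , drop = FALSE] + w * ac[sel, , drop = FALSE]
    done <- done | sel
  }
  va <- d3 * d6 - d5 * d4
  sel <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(sel)) {
    w <- (d4[sel] - d3[sel]) / ((d4[sel] - d3[sel]) + (d5[sel] - d6[sel]))
    q[sel, ] <- b[sel, , drop = FALSE] +
      w * (c3[sel, , drop = FALSE] - b[sel, , drop = FALSE])
    done <- done | sel
  }
  if (any(!done)) {
    i <- which(!done)
    denom <- va[i] + vb[i] + vc[i]
    v <- vb[i] / denom; w <- vc[i] / denom
    q[i, ] <- a[i, , drop = FALSE] + v * ab[i, , drop = FALSE] +
      w * ac[i, , drop = FALSE]
  }
  dq <- sweep(q, 2, p)
  list(d2 = rowSums(dq * dq), q = q)
}

#' Closest points on a surface mesh for a set of query points
#'
#' Exact point-to-triangle projection with a centroid-radius pruning bound:
#' the nearest mesh vertex provides an upper bound on the distance, and
#' triangles whose centroid is further than that bound plus their
#' circumscribing radius are skipped.
#'
#' @param points numeric matrix of query points.
#' @param mesh a `surface_mesh`.
#' @return list with `distance` (unsigned, mm), `closest` (points on the
#'   surface) and `triangle` (index of the closest triangle).
#' @export
closest_point_on_surface <- function(points, mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (!nrow(tr)) stop_input("mesh has no triangles")
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  cen <- (a + b + c3) / 3
  rad <- sqrt(pmax(rowSums((a - cen)^2),
                   rowSums((b - cen)^2),
                   rowSums((c3 - cen)^2)))
  np <- nrow(points)
  dist <- numeric(np)
  cl <- matrix(0, np, 3)
  tri <- integer(np)
  for (i in seq_len(np)) {
    p <- points[i, ]
    dv2 <- (v[, 1] - p[1])^2 + (v[, 2] - p[2])^2 + (v[, 3] - p[3])^2
    ub <- sqrt(min(dv2))
    dc <- sqrt((cen[, 1] - p[1])^2 + (cen[, 2] - p[2])^2 +
               (cen[, 3] - p[3])^2)
    cand <- which(dc - rad <= ub + 1e-12)
    res <- closest_on_triangles(p, a[cand, , drop = FALSE],
                                b[cand, , drop = FALSE],
                                c3[cand, , drop = FALSE])
    j <- which.min(res$d2)
    dist[i] <- sqrt(res$d2[j])
    cl[i, ] <- res$q[j, ]
    tri[i] <- cand[j]
  }
  list(distance = dist, closest = cl, triangle = tri)
}

# Kabsch: optimal rotation+translation mapping src points onto dst points
kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  S <- sweep(src, 2, cs); D <- sweep(dst, 2, cd)
  H <- crossprod(S, D)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop(errorCondition("degenerate (collinear) vertex set",
                        class = c("footform_alignment_error", "error")))
  sgn <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, sgn)) %*% t(sv$u)
  t <- cd - as.vector(R %*% cs)
  list(rotation = R, translation = t)
}

apply_rigid <- function(points, tf) {
  sweep(points %*% t(tf$rotation), 2, tf$translation, "+")
}

# signed principal frame of a point cloud: covariance eigenvectors with
# signs fixed by the skewness of the projections (right-handed)
principal_frame <- function(v) {
  c0 <- colMeans(v)
  vc <- sweep(v, 2, c0)
  eg <- eigen(crossprod(vc) / nrow(vc), symmetric = TRUE)
  A <- eg$vectors
  sk <- colMeans((vc %*% A)^3)
  sgn <- ifelse(sk < 0, -1, 1)
  A <- A %*% diag(sgn)
  if (det(A) < 0) {
    j <- which.min(abs(sk))
    A[, j] <- -A[, j]
  }
  list(center = c0, axes = A)
}

#' Rigid iterative closest point alignment
#'
#' Rigid-only ICP: nearest-neighbour vertex correspondences followed by a
#' Kabsch least-squares update, iterated until the RMS correspondence
#' distance improves by less than `tol` or `max_iter` is reached. The RMS
#' sequence is non-increasing. Two deterministic initialisations are tried -
#' centroid matching and signed principal-axes matching (which removes
#' flip-type local minima) - and the better final fit is returned.
#'
#' @param source,target `surface_mesh` objects (source is moved onto target).
#' @param max_iter maximum iterations.
#' @param tol RMS improvement tolerance (mm).
#' @return list with `transform` (`rotation` 3x3, `translation`), `aligned`
#'   (transformed source mesh), `rms` (final RMS, mm) and `rms_history`.
#' @export
icp_align <- function(source, target, max_iter = 50L, tol = 1e-8) {
  if (!nrow(source$vertices) || !nrow(target$vertices))
    stop_input("empty mesh")
  src0 <- source$vertices
  tv <- target$vertices
  inits <- list(list(rotation = diag(3),
                     translation = colMeans(tv) - colMeans(src0)))
  pf <- tryCatch({
    fs <- principal_frame(src0); ft <- principal_frame(tv)
    # all four proper sign assignments guard against flip-type local minima
    # when skewness is weak along some principal axis
    lapply(list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
           function(s) {
             R0 <- (ft$axes %*% diag(s)) %*% t(fs$axes)
             list(rotation = R0,
                  translation = ft$center - as.vector(R0 %*% fs$center))
           })
  }, error = function(e) NULL)
  if (!is.null(pf)) inits <- c(inits, pf)
  best <- NULL
  for (init in inits) {
    cur <- apply_rigid(src0, init)
    R <- init$rotation; tvec <- init$translation
    rms_hist <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      # nearest target vertex per source vertex (chunked distances)
      nn <- nearest_vertex(cur, tv)
      tf <- kabsch(src0, tv[nn, , drop = FALSE])
      new <- apply_rigid(src0, tf)
      rms <- sqrt(mean(rowSums((new - tv[nn, , drop = FALSE])^2)))
      if (rms <= prev + 1e-15) {
        cur <- new; R <- tf$rotation; tvec <- tf$translation
        rms_hist <- c(rms_hist, rms)
      } else {
        rms_hist <- c(rms_hist, prev)
        break
      }
      if (prev - rms < tol) break
      prev <- rms
    }
    fit <- list(transform = list(rotation = R, translation = tvec),
                aligned = surface_mesh(cur, source$triangles,
                                       label = source$label),
                rms = tail(rms_hist, 1), rms_history = rms_hist)
    if (is.null(best) || fit$rms < best$rms) best <- fit
  }
  best
}

nearest_vertex <- function(query, ref, chunk = 512L) {
  nq <- nrow(query)
  out <- integer(nq)
  r2 <- rowSums(ref * ref)
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    q <- query[s:e, , drop = FALSE]
    d <- outer(rowSums(q * q), r2, "+") - 2 * tcrossprod(q, ref)
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}

#' Closest-point correspondence onto a target surface
#'
#' Maps each template vertex to its exact closest point on the target
#' surface, producing a mesh with the template's connectivity draped over
#' the target geometry. Inputs should already be rigidly aligned (see
#' [icp_align()]). The mapping is idempotent on identical shapes.
#'
#' @param template,target `surface_mesh` objects.
#' @return a `surface_mesh` with the template topology and vertices on the
#'   target surface.
#' @export
correspond <- function(template, target) {
  if (!nrow(target$vertices) || !nrow(target$triangles))
    stop_input("empty target mesh")
  cp <- closest_point_on_surface(template$vertices, target)
  surface_mesh(cp$closest, template$triangles, label = target$label)
}

#' Centroid-align a set of corresponded meshes
#'
#' Translates each shape so its vertex centroid is at the origin; a pure
#' translation, so all inter-vertex distances are preserved.
#'
#' @param shapes list of `surface_mesh` objects with consistent topology.
#' @return list of centred `surface_mesh` objects.
#' @export
centroid_align <- function(shapes) {
  nv <- vapply(shapes, function(m) nrow(m$vertices), integer(1))
  if (length(unique(nv)) != 1L)
    stop_input("shapes must share topology for centroid alignment")
  lapply(shapes, function(m)
    surface_mesh(sweep(m$vertices, 2, colMeans(m$vertices)), m$triangles,
                 label = m$label))
}

#' Build a statistical shape model by PCA
#'
#' Stacks each corresponded, aligned shape as a 3V coordinate vector and
#' performs principal component analysis about the mean shape. Mode vectors
#' are orthonormal; variances are the sample covariance eigenvalues
#' (divisor n-1), non-increasing, with at most `n_shapes - 1` modes.
#'
#' @param shapes list of >= 2 corresponded `surface_mesh` objects.
#' @return object of class `ssm_model`: list with `mean` (3V vector),
#'   `modes` (3V x m orthonormal matrix), `variances` (mm^2), `scores`
#'   (n x m), `triangles`, `n_shapes`.
#' @export
build_ssm <- function(shapes) {
  if (length(shapes) < 2L) stop_input("need at least 2 shapes")
  nv <- vapply(shapes, function(m) nrow(m$vertices), integer(1))
  if (length(unique(nv)) != 1L) stop_input("shapes must share topology")
  X <- t(vapply(shapes, function(m) as.vector(t(m$vertices)),
                numeric(3 * nv[1])))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  m <- min(length(shapes) - 1L, ncol(Xc))
  modes <- sv$v[, seq_len(m), drop = FALSE]
  variances <- (sv$d[seq_len(m)]^2) / (length(shapes) - 1)
  scores <- Xc %*% modes
  structure(list(mean = mu, modes = modes, variances = variances,
                 scores = scores, triangles = shapes[[1]]$triangles,
                 n_shapes = length(shapes)),
            class = "ssm_model")
}

#' Reconstruct a shape from an SSM
#' @param model an `ssm_model`.
#' @param scores numeric vector of mode scores (defaults to the mean shape).
#' @return a `surface_mesh`.
#' @export
ssm_shape <- function(model, scores = NULL) {
  v <- model$mean
  if (!is.null(scores)) {
    m <- length(scores)
    v <- v + as.vector(model$modes[, seq_len(m), drop = FALSE] %*% scores)
  }
  surface_mesh(matrix(v, ncol = 3, byrow = TRUE), model$triangles)
}

#' @export
print.ssm_model <- function(x, ...) {
  cat("ssm_model:", x$n_shapes, "shapes,", length(x$variances), "modes\n")
  cat("  variances (mm^2):", paste(signif(x$variances, 4), collapse = " "),
      "\n")
  invisible(x)
}

#' Per-vertex error map between a reference and a morphed shape
#'
#' In signed mode (corresponded meshes sharing topology) the error is the
#' projection of each vertex displacement onto the reference outward vertex
#' normal: positive values mean the morphed vertex lies outside the reference
#' surface ("bone growth"), negative inside. In unsigned mode the error is
#' the unsigned closest-point distance from each morphed vertex to the
#' reference surface, for arbitrary mesh pairs.
#'
#' @param reference,morphed `surface_mesh` objects.
#' @param signed use the signed convention (requires shared topology).
#' @return numeric vector of per-vertex distances (mm), attribute `"range"`.
#' @export
error_map <- function(reference, morphed, signed = TRUE) {
  if (signed) {
    if (nrow(reference$vertices) != nrow(morphed$vertices) ||
        !identical(dim(reference$triangles), dim(morphed$triangles)))
      stop_input("signed error map requires corresponded meshes")
    n <- vertex_normals(reference)
    d <- rowSums((morphed$vertices - reference$vertices) * n)
  } else {
    d <- closest_point_on_surface(morphed$vertices, reference)$distance
  }
  attr(d, "range") <- range(d)
  d
}

#' Hausdorff distance summary between two surfaces
#'
#' Directed Hausdorff distances are maxima over one mesh's vertices of the
#' exact point-to-surface distance to the other mesh; the symmetric Hausdorff
#' distance is their maximum. A Gaussian summary (sample mean and sd) of the
#' pooled per-vertex distance distribution is also reported.
#'
#' @param A,B `surface_mesh` objects.
#' @return object of class `distance_summary`: list with `hausdorff_ab`,
#'   `hausdorff_ba`, `hausdorff` (mm), `gaussian_mean`, `gaussian_sd`, and
#'   the per-vertex distance vectors `dist_ab`, `dist_ba`.
#' @export
hausdorff <- function(A, B) {
  if (!nrow(A$vertices) || !nrow(B$vertices)) stop_input("empty mesh")
  dab <- closest_point_on_surface(A$vertices, B)$distance
  dba <- closest_point_on_surface(B$vertices, A)$distance
  pooled <- c(dab, dba)
  structure(list(hausdorff_ab = max(dab), hausdorff_ba = max(dba),
                 hausdorff = max(dab, dba),
                 gaussian_mean = mean(pooled),
                 gaussian_sd = sd(pooled),
                 dist_ab = dab, dist_ba = dba),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("distance_summary: Hausdorff %.4f mm (A->B %.4f, B->A %.4f)\n",
              x$hausdorff, x$hausdorff_ab, x$hausdorff_ba))
  cat(sprintf("  per-vertex distances: mean %.4f mm, sd %.4f mm\n",
              x$gaussian_mean, x$gaussian_sd))
  invisible(x)
}
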