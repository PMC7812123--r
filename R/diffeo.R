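#' Deformation model: Gaussian-kernel control points and momenta
#'
#' Parameterizes a smooth deformation as the flow of a velocity field
#' \deqn{v(x) = \sum_j K(x, c_j)\, m_j, \quad K(x, c) = \exp(-|x-c|^2/\sigma^2)}
#' integrated with explicit Euler steps over `n_timesteps`. Zero momenta give
#' the identity map exactly.
#'
#' @param control_points k x 3 matrix (mm).
#' @param momenta k x 3 matrix of momentum vectors.
#' @param kernel_width Gaussian kernel width sigma (mm), > 0.
#' @param n_timesteps number of Euler integration steps, >= 1.
#' @return object of class `deformation_model`.
#' @export
deformation_model <- function(control_points, momenta, kernel_width,
                              n_timesteps = 10) {
  control_points <- as_points(control_points)
  momenta <- as_points(momenta)
  stopifnot(nrow(control_points) == nrow(momenta), kernel_width > 0,
            n_timesteps >= 1)
  structure(list(control_points = control_points, momenta = momenta,
                 kernel_width = kernel_width,
                 n_timesteps = as.integer(n_timesteps)),
            class = "deformation_model")
}

#' @export
print.deformation_model <- function(x, ...) {
  cat("deformation_model:", nrow(x$control_points), "control points, sigma",
      x$kernel_width, "mm,", x$n_timesteps, "timesteps\n")
  invisible(x)
}

# internal: Gaussian kernel matrix between point sets
gauss_kernel <- function(X, Y, sigma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-pmax(d2, 0) / sigma^2)
}

#' Transport points through a deformation model
#'
#' Applies the same flow as the registration to arbitrary points; applying it
#' to the registration's source vertices reproduces `deformed_source`.
#' @param model a [deformation_model()].
#' @param points n x 3 matrix (mm).
#' @return n x 3 matrix of transported points.
#' @export
transport_points <- function(model, points) {
  X <- as_points(points)
  if (all(model$momenta == 0)) return(X)
  Tn <- model$n_timesteps
  for (t in seq_len(Tn)) {
    K <- gauss_kernel(X, model$control_points, model$kernel_width)
    X <- X + (K %*% model$momenta) / Tn
  }
  X
}

#' Transport a curve set through a deformation model
#'
#' Applies [transport_points()] to every polyline; labels, sides and
#' strengths are preserved bit-identically.
#' @param model a [deformation_model()].
#' @param curves a [curve_set()].
#' @return the transported [curve_set()].
#' @export
transport_curves <- function(model, curves) {
  out <- lapply(curves$curves, function(cv) {
    cv$points <- transport_points(model, cv$points)
    cv
  })
  curve_set(out, source = curves$source)
}

# --- varifold data term -------------------------------------------------

# internal: face centers and (unnormalized, area-weighted) normals
varifold_faces <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  N <- 0.5 * cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                   e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                   e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  list(C = (a + b + cc) / 3, N = N)
}

# internal: varifold inner product sum_ij k(C1i,C2j) (N1i.N2j)^2/(|N1i||N2j|)
varifold_ip <- function(f1, f2, sigma) {
  K <- gauss_kernel(f1$C, f2$C, sigma)
  dot <- tcrossprod(f1$N, f2$N)
  a <- pmax(sqrt(rowSums(f1$N^2)), 1e-12)
  b <- pmax(sqrt(rowSums(f2$N^2)), 1e-12)
  sum(K * (dot^2 / outer(a, b)))
}

#' Varifold distance between two surfaces
#'
#' Orientation-insensitive kernel metric between triangle meshes, used as the
#' registration data term.
#' @param mesh1,mesh2 [triangle_mesh()] objects.
#' @param sigma spatial kernel width (mm).
#' @return non-negative distance (squared varifold norm of the difference).
#' @export
varifold_distance <- function(mesh1, mesh2, sigma) {
  f1 <- varifold_faces(mesh1$vertices, mesh1$faces)
  f2 <- varifold_faces(mesh2$vertices, mesh2$faces)
  varifold_ip(f1, f1, sigma) - 2 * varifold_ip(f1, f2, sigma) +
    varifold_ip(f2, f2, sigma)
}

# internal: gradient of [<S,S> - 2<S,T>] wrt the S face centers and normals
varifold_grad_faces <- function(fS, fT, sigma) {
  gC <- matrix(0, nrow(fS$C), 3)
  gN <- matrix(0, nrow(fS$C), 3)
  a <- pmax(sqrt(rowSums(fS$N^2)), 1e-12)
  term <- function(fO, coef) {
    b <- pmax(sqrt(rowSums(fO$N^2)), 1e-12)
    K <- gauss_kernel(fS$C, fO$C, sigma)
    dot <- tcrossprod(fS$N, fO$N)
    phi <- dot^2 / outer(a, b)
    W <- K * phi * (-2 / sigma^2)
    gC <<- gC + coef * (fS$C * rowSums(W) - W %*% fO$C)
    A <- (K * dot / outer(a, b)) %*% fO$N * 2
    gN <<- gN + coef * (A - fS$N * (rowSums(K * phi) / a^2))
  }
  term(fS, 2)   # d<S,S>: factor 2 over single-sum gradient
  term(fT, -2)  # -2<S,T>
  list(gC = gC, gN = gN)
}

# internal: chain face-center/normal gradients back to vertex positions
varifold_grad_vertices <- function(vertices, faces, fS, g) {
  gV <- matrix(0, nrow(vertices), 3)
  cross3 <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  va <- vertices[faces[, 1], , drop = FALSE]
  vb <- vertices[faces[, 2], , drop = FALSE]
  vc <- vertices[faces[, 3], , drop = FALSE]
  addg <- function(col, contrib) {
    s <- rowsum(contrib, faces[, col], reorder = FALSE)
    idx <- as.integer(rownames(s))
    gV[idx, ] <<- gV[idx, ] + s
  }
  third <- g$gC / 3
  addg(1, third + 0.5 * cross3(vb - vc, g$gN))
  addg(2, third + 0.5 * cross3(vc - va, g$gN))
  addg(3, third + 0.5 * cross3(va - vb, g$gN))
  gV
}

#' Deformation-based registration of a source surface onto a target
#'
#' Minimizes `data_term + regularization_weight * kinetic_energy`, where the
#' deformation is the Euler flow of a Gaussian-kernel velocity field held by
#' control points on a regular grid over the source bounding box, and the
#' data term is the varifold distance between the deformed source and the
#' target, normalized by the varifold norm of the target. Momenta are
#' optimized by gradient descent with a backtracking line search from a
#' deterministic zero-momenta start, so the energy trace is non-increasing by
#' construction.
#'
#' @param source,target [triangle_mesh()] objects; `source` should already be
#'   rigidly aligned to `target` (see [align_rigid_scale()]).
#' @param kernel_width deformation kernel width (mm); deformations are smooth
#'   at this scale, chosen larger than the sulcal spacing so curves transport
#'   coherently.
#' @param data_kernel_width varifold kernel width (mm), the scale at which
#'   surface mismatch is measured.
#' @param n_control_points approximate control-point budget on the grid.
#' @param regularization_weight weight of the kinetic energy (mean
#'   `m^T K m` over control points) against the normalized data term.
#' @param n_timesteps Euler integration steps.
#' @param max_iters gradient-descent iterations.
#' @param seed unused at the deterministic default initialization; kept so a
#'   stochastic initialization stays reproducible.
#' @return object of class `registration_result`: `model`
#'   ([deformation_model()]), `deformed_source` (same face connectivity as
#'   `source`), `energy_trace` (accepted iterates, non-increasing),
#'   `final_data_term` (normalized varifold distance), `rigid_prealign`.
#' @export
register_diffeo <- function(source, target, kernel_width = 15,
                            data_kernel_width = 5, n_control_points = 1000,
                            regularization_weight = 1e-4, n_timesteps = 10,
                            max_iters = 60, seed = NULL,
                            rigid_prealign = similarity_transform()) {
  stopifnot(kernel_width > 0, data_kernel_width > 0, n_control_points >= 1)
  if (!is.null(seed)) local_seed(seed)
  V0 <- source$vertices
  Fc <- source$faces
  fT <- varifold_faces(target$vertices, target$faces)
  tnorm <- varifold_ip(fT, fT, data_kernel_width)
  if (!is.finite(tnorm) || tnorm <= 0) stop("degenerate target surface")

  # control points: regular grid over the (slightly expanded) source bbox
  lo <- apply(V0, 2, min) - kernel_width / 2
  hi <- apply(V0, 2, max) + kernel_width / 2
  spacing <- (prod(hi - lo) / n_control_points)^(1 / 3)
  repeat {
    gs <- lapply(1:3, function(k) seq(lo[k], hi[k], by = spacing))
    if (prod(lengths(gs)) <= n_control_points) break
    spacing <- spacing * 1.05
  }
  C <- as.matrix(expand.grid(gs[[1]], gs[[2]], gs[[3]]))
  colnames(C) <- NULL
  k <- nrow(C)
  Kcc <- gauss_kernel(C, C, kernel_width)
  Tn <- as.integer(n_timesteps)

  flow_states <- function(M) {
    X <- V0
    states <- vector("list", Tn + 1)
    states[[1]] <- X
    for (t in seq_len(Tn)) {
      K <- gauss_kernel(X, C, kernel_width)
      X <- X + (K %*% M) / Tn
      states[[t + 1]] <- X
    }
    states
  }
  data_term <- function(X) {
    fS <- varifold_faces(X, Fc)
    (varifold_ip(fS, fS, data_kernel_width) -
       2 * varifold_ip(fS, fT, data_kernel_width) + tnorm) / tnorm
  }
  energy <- function(M, states = NULL) {
    if (is.null(states)) states <- flow_states(M)
    data_term(states[[Tn + 1]]) +
      regularization_weight * sum((Kcc %*% M) * M) / k
  }
  grad_energy <- function(M, states) {
    X <- states[[Tn + 1]]
    fS <- varifold_faces(X, Fc)
    gf <- varifold_grad_faces(fS, fT, data_kernel_width)
    G <- varifold_grad_vertices(X, Fc, fS, gf) / tnorm
    gM <- matrix(0, k, 3)
    for (t in rev(seq_len(Tn))) {
      Xt <- states[[t]]
      K <- gauss_kernel(Xt, C, kernel_width)
      gM <- gM + crossprod(K, G) / Tn
      # backpropagate through X_{t+1} = X_t + K(X_t, C) M / Tn
      S <- K * (G %*% t(M))                       # n x k
      G <- G - (2 / (Tn * kernel_width^2)) *
        (Xt * rowSums(S) - S %*% C)
    }
    gM + regularization_weight * 2 * (Kcc %*% M) / k
  }

  M <- matrix(0, k, 3)
  states <- flow_states(M)
  E <- energy(M, states)
  trace <- E
  step <- NULL
  for (it in seq_len(max_iters)) {
    g <- grad_energy(M, states)
    gmax <- max(abs(g))
    if (!is.finite(gmax)) stop("non-finite registration gradient")
    if (gmax < 1e-12) break
    if (is.null(step)) step <- 0.5 / gmax  # first trial: ~0.5 mm momentum move
    accepted <- FALSE
    for (bt in 1:30) {
      M1 <- M - step * g
      st1 <- flow_states(M1)
      E1 <- energy(M1, st1)
      if (is.finite(E1) && E1 <= E) {
        M <- M1
        states <- st1
        E <- E1
        step <- step * 1.5
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    trace <- c(trace, E)
    if (!accepted) break
  }

  X <- states[[Tn + 1]]
  model <- deformation_model(C, M, kernel_width, Tn)
  structure(list(model = model,
                 deformed_source = triangle_mesh(X, Fc),
                 energy_trace = trace,
                 final_data_term = data_term(X),
                 rigid_prealign = rigid_prealign),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("registration_result:", length(x$energy_trace) - 1, "iterations, ",
      "final data term", format(x$final_data_term, digits = 4), "\n")
  invisible(x)
}

#' Rigid + uniform-scale alignment of two meshes (iterative closest point)
#'
#' Alternates exact closest-point correspondences from source vertices to the
#' target surface with the closed-form similarity (Umeyama) update. Only
#' steps that do not increase the mean closest-point distance are accepted,
#' so the objective is non-increasing.
#'
#' @param source,target [triangle_mesh()] objects that overlap after centroid
#'   alignment.
#' @param max_iters iteration cap.
#' @param tol stop when the mean distance improves by less than `tol` mm.
#' @param max_points subsample cap on source vertices (deterministic stride).
#' @return a [similarity_transform()] mapping source to target, with
#'   attributes `mean_dist` (final mean closest-point distance) and `trace`.
#' @export
align_rigid_scale <- function(source, target, max_iters = 300, tol = 1e-9,
                              max_points = 3000) {
  P0 <- source$vertices
  if (nrow(P0) > max_points)
    P0 <- P0[unique(round(seq(1, nrow(P0), length.out = max_points))), ,
             drop = FALSE]
  sv <- svd(sweep(P0, 2, colMeans(P0)))$d
  if (sv[3] < 1e-9 * sv[1]) stop("degenerate (flat or collinear) source mesh")
  tf <- similarity_transform()
  P <- P0
  cp <- closest_point_mesh(target, P)
  best <- mean(cp$distance)
  trace <- best
  for (it in seq_len(max_iters)) {
    Q <- cp$point
    # Umeyama similarity fit P -> Q
    mp <- colMeans(P)
    mq <- colMeans(Q)
    Pc <- sweep(P, 2, mp)
    Qc <- sweep(Q, 2, mq)
    S <- crossprod(Qc, Pc) / nrow(P)
    sv <- svd(S)
    D <- diag(3)
    if (det(sv$u) * det(sv$v) < 0) D[3, 3] <- -1
    R <- sv$u %*% D %*% t(sv$v)
    varP <- sum(Pc^2) / nrow(P)
    s <- sum(diag(D %*% diag(sv$d))) / varP
    t <- mq - s * as.vector(R %*% mp)
    cand <- compose_transform(similarity_transform(R, t, s), tf)
    Pnew <- apply_transform(cand, P0)
    cpn <- closest_point_mesh(target, Pnew)
    mnew <- mean(cpn$distance)
    if (mnew > best + 1e-12) break  # would increase the objective
    improved <- best - mnew
    tf <- cand
    P <- Pnew
    cp <- cpn
    best <- mnew
    trace <- c(trace, best)
    if (improved < tol) break
  }
  attr(tf, "mean_dist") <- best
  attr(tf, "trace") <- trace
  tf
}
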