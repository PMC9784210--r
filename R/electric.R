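# Quasi-static conduction solve: div(sigma grad phi) = 0 with Dirichlet
# voltages on the electrode and the dispersive pad, zero normal current
# elsewhere. Piecewise-linear Galerkin on the triangulation; the nonlinearity
# sigma(|E|, T) is handled by Picard (fixed-point) iteration with
# under-relaxation.

# Per-element P1 shape-function geometry, cached on first use.
elem_geometry <- function(mesh) {
  if (!is.null(mesh$cache)) {
    g <- get0("elem_geom", envir = mesh$cache)
    if (!is.null(g)) return(g)
  }
  nd <- mesh$nodes; tr <- mesh$tri
  x1 <- nd[tr[, 1], 1]; y1 <- nd[tr[, 1], 2]
  x2 <- nd[tr[, 2], 1]; y2 <- nd[tr[, 2], 2]
  x3 <- nd[tr[, 3], 1]; y3 <- nd[tr[, 3], 2]
  b <- cbind(y2 - y3, y3 - y1, y1 - y2)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1)
  A <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  g <- list(b = b, c = cc, A = A)
  if (!is.null(mesh$cache)) assign("elem_geom", g, envir = mesh$cache)
  g
}

#' Assemble the P1 stiffness matrix
#'
#' K_ij = sum_e coef_e / (4 A_e) (b_i b_j + c_i c_j): conduction with
#' coefficient `coef_elem` (sigma for the electrical problem, k for the
#' thermal one).
#'
#' @param mesh a `pef_mesh`.
#' @param coef_elem per-element coefficient (recycled if length 1).
#' @return a sparse symmetric `dgCMatrix` (n_nodes x n_nodes).
#' @export
assemble_stiffness <- function(mesh, coef_elem) {
  g <- elem_geometry(mesh)
  m <- nrow(mesh$tri)
  coef <- rep_len(coef_elem, m)
  w <- coef / (4 * g$A)
  ii <- jj <- xx <- vector("list", 9)
  k <- 1
  for (a in 1:3) for (bb in 1:3) {
    ii[[k]] <- mesh$tri[, a]
    jj[[k]] <- mesh$tri[, bb]
    xx[[k]] <- w * (g$b[, a] * g$b[, bb] + g$c[, a] * g$c[, bb])
    k <- k + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2))
}

#' Dirichlet node sets for the applied-voltage problem
#'
#' Electrode nodes are every node of the meshed metal electrode plus any node
#' on an exterior edge tagged `electrode_surface` (the whole metal is treated
#' as an equipotential); pad nodes are the nodes of `dispersive_pad` edges.
#'
#' @param mesh a `pef_mesh`.
#' @param electrode_V applied electrode voltage, V.
#' @param pad_V dispersive pad voltage, V.
#' @return list with integer `nodes` and numeric `values`.
#' @export
dirichlet_set <- function(mesh, electrode_V, pad_V = 0) {
  el_nodes <- unique(as.vector(mesh$tri[mesh$region == "electrode_metal", ]))
  e <- mesh$edges
  el_nodes <- union(el_nodes,
                    unique(c(e$n1[e$tag == "electrode_surface"],
                             e$n2[e$tag == "electrode_surface"])))
  pad_nodes <- unique(c(e$n1[e$tag == "dispersive_pad"],
                        e$n2[e$tag == "dispersive_pad"]))
  if (length(el_nodes) == 0 || length(pad_nodes) == 0)
    stop("mesh lacks electrode or dispersive-pad nodes for a Dirichlet solve")
  list(nodes = c(el_nodes, pad_nodes),
       values = c(rep(electrode_V, length(el_nodes)),
                  rep(pad_V, length(pad_nodes))))
}

#' Solve the linear conduction problem
#'
#' Galerkin P1 solution of div(sigma grad phi) = 0 with the given Dirichlet
#' set; all other exterior boundaries are natural (zero normal current). The
#' reduced system is symmetric positive definite and solved by sparse
#' Cholesky.
#'
#' @param mesh a `pef_mesh`.
#' @param sigma_elem per-element conductivity, S/m (> 0).
#' @param bc a [dirichlet_set()]-style list (`nodes`, `values`).
#' @return nodal potential vector, V.
#' @export
solve_linear_potential <- function(mesh, sigma_elem, bc) {
  if (any(sigma_elem <= 0)) stop("sigma_elem must be positive everywhere")
  if (length(bc$nodes) == 0) stop("singular system: no Dirichlet nodes")
  K <- assemble_stiffness(mesh, sigma_elem)
  dirichlet_solve(K, bc, nrow(mesh$nodes))
}

# reduced SPD solve with Dirichlet elimination; when `cache` is given the
# sparse-Cholesky symbolic analysis is reused across calls with the same
# sparsity pattern (Picard iterations, repeated pulse solves)
dirichlet_solve <- function(K, bc, n, cache = NULL) {
  fixed <- bc$nodes
  free <- setdiff(seq_len(n), fixed)
  phi <- numeric(n)
  phi[fixed] <- bc$values
  rhs <- -K[free, fixed, drop = FALSE] %*% bc$values
  Kff <- Matrix::forceSymmetric(K[free, free])
  if (is.null(cache)) {
    phi[free] <- as.numeric(Matrix::solve(Kff, rhs))
    return(phi)
  }
  fac <- get0("chol", envir = cache)
  fac <- if (is.null(fac)) Matrix::Cholesky(Kff, LDL = FALSE)
         else Matrix::update(fac, Kff)
  assign("chol", fac, envir = cache)
  phi[free] <- as.numeric(Matrix::solve(fac, rhs, system = "A"))
  phi
}

#' Per-element electric field from a nodal potential
#'
#' E = -grad(phi); constant on each linear triangle.
#'
#' @param mesh a `pef_mesh`.
#' @param phi nodal potential, V.
#' @return list with `Ex`, `Ey` and `E_mag` (V/m) per element.
#' @export
gradient_field <- function(mesh, phi) {
  g <- elem_geometry(mesh)
  ph <- cbind(phi[mesh$tri[, 1]], phi[mesh$tri[, 2]], phi[mesh$tri[, 3]])
  Ex <- -rowSums(ph * g$b) / (2 * g$A)
  Ey <- -rowSums(ph * g$c) / (2 * g$A)
  list(Ex = Ex, Ey = Ey, E_mag = sqrt(Ex^2 + Ey^2))
}

# per-element conductivity from the material law at given field/temperature
sigma_from_state <- function(mesh, table, model, E_mag_elem, T_elem) {
  sig <- numeric(nrow(mesh$tri))
  for (tag in unique(mesh$region)) {
    idx <- mesh$region == tag
    pr <- material_for(tag, table)
    sig[idx] <- effective_conductivity(pr, model, E_mag_elem[idx], T_elem[idx])
  }
  sig
}

#' Self-consistent nonlinear field solve
#'
#' Picard iteration on the field-dependent conductivity: solve with
#' sigma^(n), evaluate E, update sigma^(n+1) = sigma(|E|, T); iterate until
#' the maximum relative change of any element conductivity drops below `tol`.
#' When the change grows from one iteration to the next, the update is
#' under-relaxed by 0.5.
#'
#' @param mesh a `pef_mesh`.
#' @param table material table (see [material_table()]).
#' @param model a [sigmoid_model()].
#' @param T_nodal nodal temperature, degrees C (scalar recycled).
#' @param amplitude applied electrode voltage, V.
#' @param tol convergence tolerance on relative sigma change.
#' @param max_iter iteration cap.
#' @param E_init optional per-element field magnitude warm start, V/m.
#' @param cache optional environment carrying the Cholesky symbolic analysis
#'   across repeated solves on the same mesh.
#' @return object of class `pef_field`: `phi` (V), `Ex`, `Ey`, `E_mag` (V/m),
#'   `sigma_elem` (S/m), `iterations`, `residual` (final sigma change),
#'   `history` (per-iteration change).
#' @export
solve_selfconsistent <- function(mesh, table = material_table(),
                                 model = sigmoid_model(), T_nodal = 37,
                                 amplitude = 1000, tol = 1e-3, max_iter = 50,
                                 E_init = NULL, cache = NULL) {
  stopifnot(tol > 0)
  T_nodal <- rep_len(T_nodal, nrow(mesh$nodes))
  T_elem <- (T_nodal[mesh$tri[, 1]] + T_nodal[mesh$tri[, 2]] +
             T_nodal[mesh$tri[, 3]]) / 3
  bc <- dirichlet_set(mesh, amplitude)
  E_mag <- if (is.null(E_init)) rep(0, nrow(mesh$tri))
           else rep_len(E_init, nrow(mesh$tri))
  sigma <- sigma_from_state(mesh, table, model, E_mag, T_elem)
  history <- numeric(0)
  prev_change <- Inf
  omega <- 1   # damping factor; halved (persistently) whenever the update
               # oscillates, which happens for elements sitting on the
               # sigmoid transition
  fac_cache <- cache %||% new.env(parent = emptyenv())
  for (it in seq_len(max_iter)) {
    K <- assemble_stiffness(mesh, sigma)
    phi <- dirichlet_solve(K, bc, nrow(mesh$nodes), cache = fac_cache)
    gf <- gradient_field(mesh, phi)
    sigma_new <- sigma_from_state(mesh, table, model, gf$E_mag, T_elem)
    change <- max(abs(sigma_new - sigma) / sigma)
    history <- c(history, change)
    if (change < tol) {
      return(structure(list(phi = phi, Ex = gf$Ex, Ey = gf$Ey,
                            E_mag = gf$E_mag, sigma_elem = sigma_new,
                            iterations = it, residual = change,
                            history = history), class = "pef_field"))
    }
    if (it > 1 && change > 0.8 * prev_change) omega <- max(omega * 0.5, 0.05)
    else if (change < 0.5 * prev_change) omega <- min(1, omega * 1.5)
    sigma <- sigma + omega * (sigma_new - sigma)
    prev_change <- change
  }
  stop("self-consistent field solve did not converge in ", max_iter,
       " iterations; sigma-change history: ",
       paste(signif(history, 3), collapse = ", "))
}

#' Boundary current per unit depth
#'
#' Integral of sigma grad(phi) . n along a tagged boundary, A/m. For the
#' Dirichlet boundaries (`electrode_surface`, `dispersive_pad`) the
#' superconvergent nodal-reaction form r = K phi summed over the fixed node
#' set is used; for other tags the one-sided element flux is integrated edge
#' by edge.
#'
#' @param mesh a `pef_mesh`.
#' @param solution a `pef_field` (or list with `phi` and `sigma_elem`).
#' @param tag boundary tag.
#' @return signed current per unit depth, A/m (positive = out of the domain
#'   for the reaction form).
#' @export
boundary_current <- function(mesh, solution, tag) {
  known <- unique(c(mesh$edges$tag, "electrode_surface", "dispersive_pad"))
  if (!tag %in% known) stop("unknown boundary tag: ", tag)
  if (tag %in% c("electrode_surface", "dispersive_pad")) {
    K <- assemble_stiffness(mesh, solution$sigma_elem)
    r <- as.numeric(K %*% solution$phi)
    e <- mesh$edges
    if (tag == "electrode_surface") {
      nodes <- unique(c(as.vector(mesh$tri[mesh$region == "electrode_metal", ]),
                        e$n1[e$tag == "electrode_surface"],
                        e$n2[e$tag == "electrode_surface"]))
    } else {
      nodes <- unique(c(e$n1[e$tag == "dispersive_pad"],
                        e$n2[e$tag == "dispersive_pad"]))
    }
    return(sum(r[nodes]))
  }
  e <- mesh$edges[mesh$edges$tag == tag, , drop = FALSE]
  if (nrow(e) == 0) return(0)
  gf <- gradient_field(mesh, solution$phi)
  # adjacent element of each tagged edge
  tot <- 0
  for (k in seq_len(nrow(e))) {
    hit <- which(rowSums(matrix(mesh$tri %in% c(e$n1[k], e$n2[k]),
                                ncol = 3), na.rm = TRUE) == 2)
    el <- hit[1]
    p1 <- mesh$nodes[e$n1[k], ]; p2 <- mesh$nodes[e$n2[k], ]
    tvec <- p2 - p1
    len <- sqrt(sum(tvec^2))
    nvec <- c(tvec[2], -tvec[1]) / len
    flux <- solution$sigma_elem[el] * (-gf$Ex[el] * nvec[1] - gf$Ey[el] * nvec[2])
    tot <- tot + abs(flux) * len
  }
  tot
}
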