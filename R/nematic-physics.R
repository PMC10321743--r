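# Post-discovery physics: stresses, strong-form residual maps, bounding-layer
# flow profiles, Rayleigh friction, and the buckling length scale of the
# extending-bundle instability.

#' Active stress field
#'
#' `sigma^a = alpha Qbar`: symmetric traceless, proportional to the
#' traceless nematic tensor.  `alpha > 0` corresponds to an extensile
#' system.
#'
#' @param Qbar array `(nx, ny, nt, 2, 2)` (from [derived_fields()]).
#' @param alpha activity coefficient.
#' @return array of the same shape.
#' @export
active_stress <- function(Qbar, alpha) alpha * Qbar

#' Anisotropic viscous stress field
#'
#' `sigma^v = mu_a (Abar : Qbar) Qbar`: the single-Leslie-coefficient form
#' (beta_1 only; nu_4 = beta_2 = 0) that the discovered stress balance
#' selects.  Symmetric traceless by construction.
#'
#' @param Qbar,Abar arrays `(nx, ny, nt, 2, 2)`.
#' @param mu_a anisotropic viscosity prefactor.
#' @return array of the same shape.
#' @export
viscous_stress <- function(Qbar, Abar, mu_a) {
  tr <- Abar[, , , 1, 1] * Qbar[, , , 1, 1] + Abar[, , , 2, 2] * Qbar[, , , 2, 2] +
    Abar[, , , 1, 2] * Qbar[, , , 1, 2] + Abar[, , , 2, 1] * Qbar[, , , 2, 1]
  out <- Qbar
  for (i in 1:2) for (j in 1:2) out[, , , i, j] <- mu_a * tr * Qbar[, , , i, j]
  out
}

#' General Leslie viscous stress (two-dimensional form)
#'
#' `sigma^v_ij = nu4 A_ij + beta1 (A_kl n_k n_l) n_i n_j +
#'  beta2 (A_ik n_k n_j + A_jk n_k n_i)`, with `A` the traceless strain
#' (the Leslie theory lives in incompressible flow, where the two
#' coincide).  With `nu4 = beta2 = 0` its deviatoric part coincides with
#' [viscous_stress()] with `mu_a = beta1` pointwise, an exact identity.
#'
#' @param fields a [field_sequence()].
#' @param nu4,beta1,beta2 Leslie viscosities.
#' @return array `(nx, ny, nt, 2, 2)`.
#' @export
leslie_stress <- function(fields, nu4 = 0, beta1 = 1, beta2 = 0) {
  df <- derived_fields(fields)
  n <- fields$n
  A <- df$Abar
  nAn <- A[, , , 1, 1] * n[, , , 1]^2 + 2 * A[, , , 1, 2] * n[, , , 1] * n[, , , 2] +
    A[, , , 2, 2] * n[, , , 2]^2
  out <- array(0, dim(A))
  An <- array(0, c(dim(n)[1:3], 2L))
  for (i in 1:2) An[, , , i] <- A[, , , i, 1] * n[, , , 1] + A[, , , i, 2] * n[, , , 2]
  for (i in 1:2) for (j in 1:2) {
    out[, , , i, j] <- nu4 * A[, , , i, j] +
      beta1 * nAn * n[, , , i] * n[, , , j] +
      beta2 * (An[, , , i] * n[, , , j] + An[, , , j] * n[, , , i])
  }
  out
}

deviatoric <- function(S) {
  tr <- (S[, , , 1, 1] + S[, , , 2, 2]) / 2
  S[, , , 1, 1] <- S[, , , 1, 1] - tr
  S[, , , 2, 2] <- S[, , , 2, 2] - tr
  S
}

#' Strong-form stress-balance residual maps
#'
#' Pointwise maps of the rank-2 balance `(Abar : Qbar) Qbar + c5 Qbar` and
#' its scalar contraction `Abar : Qbar + c5`, with mask-weighted summary
#' statistics.
#'
#' @param fields a [field_sequence()].
#' @param c5 stress-balance coefficient (the negative extension rate).
#' @param mask optional mask object or array.
#' @return list with `tensor` (array `(nx,ny,nt,2,2)`), `scalar` (array),
#'   and `summary` (masked RMS of each, normalized by the RMS term scale).
#' @export
stress_balance_residual <- function(fields, c5, mask = NULL) {
  df <- derived_fields(fields)
  sv <- viscous_stress(df$Qbar, df$Abar, 1)
  tens <- sv + c5 * df$Qbar
  trQA <- df$Abar[, , , 1, 1] * df$Qbar[, , , 1, 1] +
    df$Abar[, , , 2, 2] * df$Qbar[, , , 2, 2] +
    2 * df$Abar[, , , 1, 2] * df$Qbar[, , , 1, 2]
  scal <- trQA + c5
  w <- if (is.null(mask)) array(1, dim(scal)) else if (inherits(mask, "field_mask")) mask$psi else mask
  sw <- sum(w)
  if (sw == 0) {
    return(list(tensor = tens, scalar = scal,
                summary = list(empty = TRUE)))
  }
  rms <- function(a) sqrt(sum(w * a^2) / sw)
  scale_t <- max(rms(sv[, , , 1, 1]), rms(c5 * df$Qbar[, , , 1, 1]), .Machine$double.eps)
  scale_s <- max(rms(trQA), abs(c5), .Machine$double.eps)
  list(tensor = tens, scalar = scal,
       summary = list(empty = FALSE,
                      tensor_rel_rms = rms(tens[, , , 1, 1]) / scale_t,
                      scalar_rel_rms = rms(scal) / scale_s))
}

#' Observed and reconstructed angular velocity of the director
#'
#' The observed map is `dtheta/dt = eps_ij n_i dt n_j` from sign-aligned
#' time differences; the reconstruction inserts the director equation,
#' `-(c1 (u.grad)n + c2 Omega n + c3 Pperp Abar n)`, contracted the same
#' way.  Both maps are even in n, hence gauge invariant.
#'
#' @param fields a [field_sequence()].
#' @param coef director-equation coefficients `c(c1, c2, c3)`.
#' @return list with arrays `observed` and `reconstructed`.
#' @export
angular_velocity_map <- function(fields, coef = c(1, -1, -1)) {
  g <- fields$grid
  h <- grid_spacing(g)
  n <- fields$n
  dtn <- director_diff(n, 3L, h[3])
  observed <- n[, , , 1] * dtn[, , , 2] - n[, , , 2] * dtn[, , , 1]
  df <- derived_fields(fields)
  dxn <- director_diff(n, 1L, h[1])
  dyn <- director_diff(n, 2L, h[2])
  adv <- array(0, dim(n))
  for (cc in 1:2) {
    adv[, , , cc] <- fields$u[, , , 1] * dxn[, , , cc] + fields$u[, , , 2] * dyn[, , , cc]
  }
  Abar_n <- array(0, dim(n)); Om_n <- array(0, dim(n))
  for (i in 1:2) {
    Abar_n[, , , i] <- df$Abar[, , , i, 1] * n[, , , 1] + df$Abar[, , , i, 2] * n[, , , 2]
    Om_n[, , , i] <- df$Omega[, , , i, 1] * n[, , , 1] + df$Omega[, , , i, 2] * n[, , , 2]
  }
  nAn <- n[, , , 1] * Abar_n[, , , 1] + n[, , , 2] * Abar_n[, , , 2]
  rhs <- array(0, dim(n))
  for (i in 1:2) {
    proj <- Abar_n[, , , i] - n[, , , i] * nAn
    rhs[, , , i] <- -(coef[1] * adv[, , , i] + coef[2] * Om_n[, , , i] + coef[3] * proj)
  }
  reconstructed <- n[, , , 1] * rhs[, , , 2] - n[, , , 2] * rhs[, , , 1]
  list(observed = observed, reconstructed = reconstructed)
}

#' Rayleigh friction coefficient of the bounding fluid layers
#'
#' `eta_f = mu_t / h_t + mu_b / h_b`: linear shear profiles in the two
#' layers exert an interfacial stress `-eta_f u`.
#'
#' @param mu_t,mu_b dynamic viscosities of the top and bottom layers (Pa s).
#' @param h_t,h_b layer thicknesses (m).
#' @return friction coefficient (Pa s / m).
#' @export
friction_coefficient <- function(mu_t, h_t, mu_b, h_b) {
  if (any(c(mu_t, h_t, mu_b, h_b) <= 0)) stop("layer parameters must be positive")
  mu_t / h_t + mu_b / h_b
}

#' Linear bounding-layer flow profile
#'
#' Velocity at height `z` above (below) the interface: linear interpolation
#' between the interfacial flow at `z = 0` and no-slip walls at `z = h_t`
#' and `z = -h_b`.
#'
#' @param u_interface interfacial velocity (any numeric shape).
#' @param z height (scalar), in `[-h_b, h_t]`.
#' @param mu_t,h_t,mu_b,h_b layer parameters.
#' @return velocity of the same shape as `u_interface`.
#' @export
layer_flow_profile <- function(u_interface, z, mu_t, h_t, mu_b, h_b) {
  if (z > h_t || z < -h_b) stop("z outside the fluid layers")
  if (z >= 0) (1 - z / h_t) * u_interface else (1 + z / h_b) * u_interface
}

#' Interfacial shear stress of the layer profiles
#'
#' `sigma_z = mu_t dz u^t - mu_b dz u^b = -eta_f u_interface`: the linear
#' profiles reduce to Rayleigh friction on the interfacial flow.
#'
#' @inheritParams layer_flow_profile
#' @return stress with the same shape as `u_interface`.
#' @export
layer_interface_stress <- function(u_interface, mu_t, h_t, mu_b, h_b) {
  -(mu_t / h_t + mu_b / h_b) * u_interface
}

#' Buckling length scale of extending bundles
#'
#' Balancing the viscous force on a bundle of radius `r` and length `L`
#' extending at rate `Edot` against the Euler buckling threshold of a rod
#' with Young's modulus `E_Y` gives `L = r * ((h / r) * E_Y / (mu * Edot))^(1/4)`,
#' with `h` and `mu` the thickness and viscosity of the more dissipative
#' bounding layer.  A scaling estimate: the prefactor is set to 1.
#'
#' @param r bundle radius (m).
#' @param E_Y Young's modulus (Pa).
#' @param mu layer viscosity (Pa s).
#' @param h layer thickness (m).
#' @param Edot extension rate (1/s).
#' @return length (m).
#' @export
buckling_length <- function(r, E_Y, mu, h, Edot) {
  vals <- c(r, E_Y, mu, h, Edot)
  if (any(!is.finite(vals)) || any(vals <= 0)) stop("all parameters must be positive")
  r * ((h / r) * E_Y / (mu * Edot))^(1 / 4)
}

#' Strong-form residual maps of discovered relations
#'
#' Evaluates each relation pointwise with the same stencils used for
#' discovery and reports masked and unmasked summaries relative to the
#' relation's own term scale.
#'
#' @param fields a [field_sequence()].
#' @param relations list of `spider_relation`s.
#' @param library the `term_library` holding the relations' terms.
#' @param mask optional mask.
#' @return list per relation: `map` (residual array, first component),
#'   `rel_rms` (masked RMS over the term scale), `rel_rms_unmasked`.
#' @export
check_relations_strong_form <- function(fields, relations, library, mask = NULL) {
  ctx <- eval_context(fields)
  w <- if (is.null(mask)) NULL else if (inherits(mask, "field_mask")) mask$psi else mask
  keys <- vapply(library$terms, function(t) t$key, character(1))
  lapply(relations, function(rel) {
    terms <- library$terms[match(rel$keys, keys)]
    comps <- class_components(terms[[1]]$class)
    num2m <- 0; num2u <- 0; scale2 <- 0; swm <- 0; swu <- 0
    map1 <- NULL
    for (cc in comps) {
      tot <- array(0, ctx$dims)
      tsc <- 0
      for (r in seq_along(terms)) {
        arr <- rel$coefs[r] * term_component(ctx, terms[[r]], cc)
        tot <- tot + arr
        tsc <- max(tsc, sqrt(mean(arr^2)))
      }
      if (is.null(map1)) map1 <- tot
      scale2 <- max(scale2, tsc)
      num2u <- num2u + sum(tot^2); swu <- swu + length(tot)
      if (!is.null(w)) { num2m <- num2m + sum(w * tot^2); swm <- swm + sum(w) }
    }
    if (!is.null(w) && swm == 0) {
      return(list(map = map1, empty_mask = TRUE))
    }
    list(map = map1,
         rel_rms = if (is.null(w)) sqrt(num2u / swu) / max(scale2, .Machine$double.eps)
                   else sqrt(num2m / swm) / max(scale2, .Machine$double.eps),
         rel_rms_unmasked = sqrt(num2u / swu) / max(scale2, .Machine$double.eps),
         empty_mask = FALSE)
  })
}

#' Plot a residual or field map as a PNG panel
#'
#' @param map numeric matrix or 3D array (a time slice is taken).
#' @param path output PNG path.
#' @param slice time index for 3D input (default middle).
#' @param main plot title.
#' @export
save_map_png <- function(map, path, slice = NULL, main = "") {
  if (length(dim(map)) == 3L) {
    if (is.null(slice)) slice <- ceiling(dim(map)[3] / 2)
    map <- map[, , slice]
  }
  grDevices::png(path, width = 640, height = 600)
  on.exit(grDevices::dev.off())
  graphics::image(map, main = main, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"))
  invisible(path)
}
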