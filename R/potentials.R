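#' Toy potential specifications
#'
#' Describes one of the built-in analytic potentials.  These stand in for a
#' molecular force field so that every stage of the pulling machinery can be
#' verified against exact oracles.
#'
#' Available kinds and their parameters (all energies kcal/mol, lengths
#' Angstrom):
#' \describe{
#'   \item{\code{free}}{no potential, \eqn{U \equiv 0}; parameter
#'     \code{dimension} (default 1).}
#'   \item{\code{harmonic}}{\eqn{U = a x^2 / 2} summed over coordinates;
#'     parameter \code{a} [kcal/mol/A^2].}
#'   \item{\code{double_well}}{\eqn{U = h ((x/w)^2 - 1)^2}; parameters
#'     \code{h} (barrier height) and \code{w} (half well separation).}
#'   \item{\code{tilted_double_well}}{double well plus a linear tilt
#'     \eqn{c x}; parameters \code{h}, \code{w}, \code{c}.}
#'   \item{\code{bead_spring_helix}}{a 3D chain of \code{n_beads} beads with
#'     harmonic bonds (\code{k_bond}, rest length \code{r0}) and attractive
#'     Gaussian contact wells between beads \eqn{i} and \eqn{i+4}
#'     (depth \code{eps}, centre \code{r_contact}, width
#'     \code{sigma_contact}), a minimal caricature of helical i->i+4
#'     contacts.}
#' }
#'
#' @param kind one of \code{"free"}, \code{"harmonic"}, \code{"double_well"},
#'   \code{"tilted_double_well"}, \code{"bead_spring_helix"}
#' @param ... named parameters for the chosen kind (see Details)
#' @param dimension system dimension; defaults to 1 (or \code{3 * n_beads}
#'   for the bead chain, which may not be overridden)
#' @return an object of class \code{"potential_spec"}
#' @export
potential_spec <- function(kind, ..., dimension = NULL) {
  kinds <- c(free = 0L, harmonic = 1L, double_well = 2L,
             tilted_double_well = 3L, bead_spring_helix = 4L)
  if (!is.character(kind) || length(kind) != 1L || !kind %in% names(kinds)) {
    stop("configuration error: unknown potential kind ",
         deparse(substitute(kind)), "; field 'kind' must be one of: ",
         paste(names(kinds), collapse = ", "), call. = FALSE)
  }
  params <- list(...)
  need <- switch(kind,
    free = character(0),
    harmonic = "a",
    double_well = c("h", "w"),
    tilted_double_well = c("h", "w", "c"),
    bead_spring_helix = "n_beads")
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("configuration error: missing parameter(s) for kind '", kind,
         "': ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (kind == "bead_spring_helix") {
    defaults <- list(k_bond = 100, r0 = 1.5, eps = 2,
                     r_contact = 2.2, sigma_contact = 0.5)
    params <- modifyList(defaults, params)
    nb <- as.integer(params$n_beads)
    if (nb < 2) stop("configuration error: n_beads must be >= 2",
                     call. = FALSE)
    if (!is.null(dimension) && dimension != 3L * nb) {
      stop("configuration error: bead_spring_helix dimension must equal ",
           "3 * n_beads", call. = FALSE)
    }
    dimension <- 3L * nb
  }
  if (is.null(dimension)) dimension <- 1L
  dimension <- as.integer(dimension)
  if (dimension < 1L) stop("configuration error: dimension must be >= 1",
                           call. = FALSE)
  for (nm in intersect(names(params), c("a", "h", "k_bond", "eps"))) {
    if (params[[nm]] < 0) {
      stop("configuration error: parameter '", nm, "' must be >= 0",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, kind_code = kinds[[kind]], params = params,
                 dimension = dimension),
            class = "potential_spec")
}

#' Build an evaluatable potential model
#'
#' Returns an object exposing the energy \eqn{U(x)} and its gradient
#' \eqn{\nabla U(x)}, together with the default reaction-coordinate
#' definition (identity for 1D systems, first-to-last bead distance for the
#' bead chain).
#'
#' @param spec a [potential_spec()]
#' @return an object of class \code{"potential_model"}
#' @export
make_potential <- function(spec) {
  if (!inherits(spec, "potential_spec")) {
    spec <- do.call(potential_spec, spec)
  }
  pvec <- switch(spec$kind,
    free = numeric(0),
    harmonic = spec$params$a,
    double_well = c(spec$params$h, spec$params$w),
    tilted_double_well = c(spec$params$h, spec$params$w, spec$params$c),
    bead_spring_helix = with(spec$params,
      c(n_beads, k_bond, r0, eps, r_contact, sigma_contact)))
  rc <- if (spec$kind == "bead_spring_helix") {
    list(type = 1L, ai = 0L, aj = as.integer(spec$params$n_beads) - 1L)
  } else {
    list(type = 0L, ai = 0L, aj = 0L)
  }
  structure(list(kind = spec$kind, kind_code = spec$kind_code,
                 params_vec = as.numeric(pvec), dimension = spec$dimension,
                 rc = rc, spec = spec),
            class = "potential_model")
}

#' Evaluate potential energy
#'
#' @param potential a [make_potential()] model
#' @param x coordinate vector of length \code{potential$dimension}
#' @return energy in kcal/mol
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "potential_model"),
            length(x) == potential$dimension)
  cpp_pot_energy(potential$kind_code, potential$params_vec, as.numeric(x))
}

#' Evaluate potential gradient
#'
#' @inheritParams potential_energy
#' @return gradient vector in kcal/mol/A
#' @export
potential_gradient <- function(potential, x) {
  stopifnot(inherits(potential, "potential_model"),
            length(x) == potential$dimension)
  cpp_pot_gradient(potential$kind_code, potential$params_vec, as.numeric(x))
}

#' Reaction coordinate value of a configuration
#'
#' @inheritParams potential_energy
#' @return the reaction coordinate \eqn{\xi(x)} in Angstrom
#' @export
reaction_coordinate <- function(potential, x) {
  cpp_rc_value(potential$rc$type, potential$rc$ai, potential$rc$aj,
               as.numeric(x))
}

#' @export
print.potential_model <- function(x, ...) {
  cat("<potential_model>", x$kind, "dimension", x$dimension, "\n")
  invisible(x)
}
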