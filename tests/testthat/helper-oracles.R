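# Shared test fixtures and independent oracles.

kT300 <- adaptivepull::kB * 300

# Brute-force O(n^3)-style hydrogen-bond enumeration, independent of
# detect_hbonds internals: plain loops over every donor/hydrogen/acceptor
# triple with direct coordinate arithmetic.
brute_force_hbonds <- function(frame, d_cut = 4, angle_cut = 140) {
  a <- frame$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rownames(xyz) <- a$id
  res <- list()
  for (li in seq_len(nrow(frame$h_links))) {
    d_id <- frame$h_links$donor[li]
    h_id <- frame$h_links$hydrogen[li]
    for (acc_row in which(a$role %in% c("acceptor", "donor_acceptor"))) {
      a_id <- a$id[acc_row]
      if (a_id == d_id) next
      ad <- a[match(d_id, a$id), ]
      aa <- a[acc_row, ]
      if (ad$segment == aa$segment && ad$resid == aa$resid) next
      D <- xyz[as.character(d_id), ]
      H <- xyz[as.character(h_id), ]
      A <- xyz[as.character(a_id), ]
      dist <- sqrt(sum((D - A)^2))
      if (dist > d_cut) next
      v1 <- D - H; v2 <- A - H
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < angle_cut) next
      res[[length(res) + 1L]] <- data.frame(donor = d_id, hydrogen = h_id,
                                            acceptor = a_id)
    }
  }
  if (!length(res)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

# random 3D rotation matrix (seeded by caller)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_frame <- function(frame, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
  frame$atoms$x <- xyz[, 1]
  frame$atoms$y <- xyz[, 2]
  frame$atoms$z <- xyz[, 3]
  frame
}

# standard toy setups
harmonic_system <- function(a = 1, x0 = 0) {
  list(potential = make_potential(potential_spec("harmonic", a = a)),
       state = system_state(x0))
}

toy_params <- function(temperature = 300, friction = 5, timestep = 0.002,
                       masses = 1) {
  langevin_params(temperature, friction, timestep, masses)
}
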