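# Geometric hydrogen-bond detection and work-weighted contact profiling.

.hb_classes <- c("i3", "i4", "i5", "other_intrapeptide", "peptide_solvent")

#' Geometric hydrogen-bond detection
#'
#' Emits every (donor, hydrogen, acceptor) triple with donor-acceptor
#' heavy-atom distance at most \code{d_cut} and hydrogen-bond angle at
#' least \code{angle_cut}.  The angle is the standard D-H...A angle with
#' vertex at the hydrogen; the vertex is configurable because the
#' distance/angle convention varies between analysis tools (a message is
#' emitted when the non-default vertex is chosen).  Pairs within the same
#' residue are excluded, as is donor == acceptor.
#'
#' @param frame a [structure_frame()]
#' @param d_cut donor-acceptor distance cutoff [A] (default 4)
#' @param angle_cut angle cutoff [degrees] (default 140)
#' @param vertex angle vertex: \code{"hydrogen"} (D-H...A, default) or
#'   \code{"donor"} (H-D...A)
#' @return data.frame with columns donor, hydrogen, acceptor, distance,
#'   angle (possibly zero rows)
#' @export
detect_hbonds <- function(frame, d_cut = 4, angle_cut = 140,
                          vertex = c("hydrogen", "donor")) {
  stopifnot(inherits(frame, "structure_frame"))
  vertex <- match.arg(vertex)
  if (vertex != "hydrogen") {
    message("detect_hbonds: using non-default angle vertex '", vertex, "'")
  }
  a <- frame$atoms
  links <- frame$h_links
  don_role <- a$role[match(links$donor, a$id)]
  if (any(!don_role %in% c("donor", "donor_acceptor"))) {
    stop("labelling error: hydrogen without a linked donor-heavy atom")
  }
  acc_ids <- a$id[a$role %in% c("acceptor", "donor_acceptor")]
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0))
  if (nrow(links) == 0L || length(acc_ids) == 0L) return(empty)

  xyz <- as.matrix(a[, c("x", "y", "z")])
  rownames(xyz) <- a$id
  runit <- paste(a$segment, a$resid)  # residue identity across segments
  names(runit) <- a$id

  pairs <- expand.grid(li = seq_len(nrow(links)),
                       ai = seq_along(acc_ids))
  d_id <- links$donor[pairs$li]
  h_id <- links$hydrogen[pairs$li]
  a_id <- acc_ids[pairs$ai]
  keep <- d_id != a_id & runit[as.character(d_id)] != runit[as.character(a_id)]
  d_id <- d_id[keep]; h_id <- h_id[keep]; a_id <- a_id[keep]
  if (!length(d_id)) return(empty)

  D <- xyz[as.character(d_id), , drop = FALSE]
  H <- xyz[as.character(h_id), , drop = FALSE]
  A <- xyz[as.character(a_id), , drop = FALSE]
  dist <- sqrt(rowSums((D - A)^2))
  keep <- dist <= d_cut
  if (!any(keep)) return(empty)
  D <- D[keep, , drop = FALSE]; H <- H[keep, , drop = FALSE]
  A <- A[keep, , drop = FALSE]
  d_id <- d_id[keep]; h_id <- h_id[keep]; a_id <- a_id[keep]
  dist <- dist[keep]
  if (vertex == "hydrogen") {
    v1 <- D - H; v2 <- A - H
  } else {
    v1 <- H - D; v2 <- A - D
  }
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  keep <- ang >= angle_cut
  out <- data.frame(donor = d_id[keep], hydrogen = h_id[keep],
                    acceptor = a_id[keep], distance = dist[keep],
                    angle = ang[keep])
  rownames(out) <- NULL
  out
}

#' Classify hydrogen bonds into helical contact classes
#'
#' Intrapeptide bonds between donor residue i and acceptor residue j are
#' classed by the unsigned offset |j - i|: 3 (3-10 helix), 4 (alpha helix),
#' 5 (pi helix), anything else \code{other_intrapeptide}.  A bond with
#' exactly one solvent partner is \code{peptide_solvent}; solvent-solvent
#' bonds are not counted.
#'
#' @param bonds output of [detect_hbonds()] on the same frame
#' @param frame the [structure_frame()]
#' @return named integer vector of per-class counts (classes i3, i4, i5,
#'   other_intrapeptide, peptide_solvent), with the classed bond table as
#'   attribute \code{"bonds"}
#' @export
classify_contacts <- function(bonds, frame) {
  a <- frame$atoms
  counts <- setNames(integer(length(.hb_classes)), .hb_classes)
  if (nrow(bonds) == 0L) {
    attr(counts, "bonds") <- cbind(bonds, class = character(0))
    return(counts)
  }
  di <- match(bonds$donor, a$id)
  ai <- match(bonds$acceptor, a$id)
  d_sol <- a$segment[di] == "SOL"
  a_sol <- a$segment[ai] == "SOL"
  off <- abs(a$resid[ai] - a$resid[di])
  cls <- ifelse(d_sol & a_sol, NA_character_,
         ifelse(xor(d_sol, a_sol), "peptide_solvent",
         ifelse(off == 3, "i3",
         ifelse(off == 4, "i4",
         ifelse(off == 5, "i5", "other_intrapeptide")))))
  tab <- table(factor(cls, levels = .hb_classes))
  counts[] <- as.integer(tab)
  classed <- cbind(bonds, class = cls)
  attr(counts, "bonds") <- classed[!is.na(cls), , drop = FALSE]
  counts
}

#' Work-weighted hydrogen-bond profile
#'
#' At each extension grid point, averages per-trajectory contact counts
#' with Jarzynski weights \eqn{w_i \propto e^{-W_i / k_B T}} (normalized in
#' log space; equal works give the plain arithmetic mean), using each
#' trajectory's accumulated work at that extension.  A plain-mean mode is
#' provided for comparison.
#'
#' @param counts 3-dimensional array [trajectory, extension, class] of raw
#'   contact counts; the class dimension must carry dimnames
#' @param works numeric matrix [trajectory, extension] of accumulated work
#'   [kcal/mol], or a vector of per-trajectory end works applied at every
#'   extension
#' @param temperature temperature [K]
#' @param extension extension grid [A]; defaults to column index
#' @param weighting \code{"jarzynski"} (default) or \code{"plain"}
#' @return object of class \code{"hbond_profile"}: list with
#'   \code{extension}, \code{mean} (extension x class matrix), \code{raw}
#'   (the input counts), \code{weighting}
#' @export
work_weighted_profile <- function(counts, works, temperature,
                                  extension = NULL,
                                  weighting = c("jarzynski", "plain")) {
  weighting <- match.arg(weighting)
  if (length(dim(counts)) != 3L) {
    stop("counts must be a [trajectory, extension, class] array")
  }
  n_traj <- dim(counts)[1L]
  n_ext <- dim(counts)[2L]
  if (is.null(extension)) extension <- seq_len(n_ext)
  if (!is.matrix(works)) {
    works <- matrix(works, nrow = n_traj, ncol = n_ext)
  }
  if (nrow(works) != n_traj || ncol(works) != n_ext) {
    stop("works must align with counts by trajectory and extension")
  }
  if (any(!is.finite(works))) stop("non-finite works")
  kT <- kB * temperature
  cls <- dimnames(counts)[[3L]]
  mean_mat <- matrix(NA_real_, n_ext, dim(counts)[3L],
                     dimnames = list(NULL, cls))
  for (g in seq_len(n_ext)) {
    w <- if (weighting == "plain") {
      rep(1 / n_traj, n_traj)
    } else {
      lw <- -works[, g] / kT
      lw <- lw - max(lw)  # stable log-space normalization
      exp(lw) / sum(exp(lw))
    }
    cmat <- matrix(counts[, g, ], nrow = n_traj)  # traj x class
    mean_mat[g, ] <- as.numeric(crossprod(cmat, w))
  }
  structure(list(extension = extension, mean = mean_mat, raw = counts,
                 weighting = weighting),
            class = "hbond_profile")
}

#' @export
print.hbond_profile <- function(x, ...) {
  cat(sprintf("<hbond_profile> %d extensions x %d classes (%s weighting)\n",
              nrow(x$mean), ncol(x$mean), x$weighting))
  invisible(x)
}

#' Two-dimensional hydrogen-bond histogram
#'
#' Integer-binned density over (peptide-peptide, peptide-solvent) hydrogen
#' bond counts; the bin mass equals the number of input frames.
#'
#' @param pp,ps non-negative integer vectors of intrapeptide and
#'   peptide-solvent totals, one element per frame
#' @return integer matrix with rownames the intrapeptide counts and
#'   colnames the peptide-solvent counts
#' @export
hbond_histogram_2d <- function(pp, ps) {
  if (length(pp) != length(ps)) stop("pp and ps lengths differ")
  if (any(pp < 0) || any(ps < 0)) stop("counts must be >= 0")
  f1 <- factor(pp, levels = 0:max(pp, 0))
  f2 <- factor(ps, levels = 0:max(ps, 0))
  m <- as.matrix(table(f1, f2))
  names(dimnames(m)) <- c("peptide_peptide", "peptide_solvent")
  storage.mode(m) <- "integer"
  m
}

#' Effective peptide-solvent hydrogen bonds around a fixed peptide
#'
#' Given an ensemble of solvated frames whose peptide coordinates are all
#' identical to the fixed reference frame (asserted), returns the ensemble
#' mean of the peptide-solvent hydrogen-bond count.  The intrapeptide
#' counts are asserted invariant across the ensemble, since the peptide
#' does not move.
#'
#' @param fixed_frame the reference peptide [structure_frame()]
#' @param ensemble list of solvated [structure_frame()]s of that peptide
#' @param d_cut,angle_cut detection thresholds
#' @return the mean peptide-solvent count (numeric), with per-member counts
#'   as attribute \code{"per_member"} and the common intrapeptide count as
#'   attribute \code{"intrapeptide"}
#' @export
effective_solvent_hbonds <- function(fixed_frame, ensemble, d_cut = 4,
                                     angle_cut = 140) {
  stopifnot(length(ensemble) >= 1L)
  ref <- fixed_frame$atoms[fixed_frame$atoms$segment == "PEP", ]
  ref_xyz <- as.matrix(ref[, c("x", "y", "z")])
  intrapep <- NULL
  ps <- numeric(length(ensemble))
  for (j in seq_along(ensemble)) {
    fr <- ensemble[[j]]
    pep <- fr$atoms[fr$atoms$segment == "PEP", ]
    if (nrow(pep) != nrow(ref) ||
        max(abs(as.matrix(pep[, c("x", "y", "z")]) - ref_xyz)) > 1e-9) {
      stop("contract violation: ensemble member ", j,
           " has peptide coordinates differing from the fixed frame")
    }
    counts <- classify_contacts(detect_hbonds(fr, d_cut, angle_cut), fr)
    intra <- sum(counts[c("i3", "i4", "i5", "other_intrapeptide")])
    if (is.null(intrapep)) {
      intrapep <- intra
    } else if (intra != intrapep) {
      stop("contract violation: intrapeptide count changed across the ",
           "ensemble (", intrapep, " vs ", intra, ")")
    }
    ps[j] <- counts[["peptide_solvent"]]
  }
  structure(mean(ps), per_member = ps, intrapeptide = intrapep)
}
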