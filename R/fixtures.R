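# Synthetic structure fixtures: ideal polyalanine-like backbones built from
# internal coordinates, and pseudo-solvated frames for exercising the
# hydrogen-bond counting logic.  Geometry uses standard backbone bond
# lengths/angles (Engh-Huber-like values).

.geom <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231, b_NH = 1.01,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7,
  a_CA_C_O = 120.8, a_C_N_H = 119.5,
  b_OW_HW = 0.9572, a_HW_OW_HW = 104.52)

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) v / sqrt(sum(v * v))

# Place atom D bonded to C with |CD| = bond, angle(B,C,D) = angle [deg],
# torsion(A,B,C,D) = torsion [deg] (standard NeRF construction).
.place_atom <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  bc <- .unit(C - B)
  n <- .unit(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  d <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Torsion angle (degrees, IUPAC sign convention) of four points.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Labelled structure frame
#'
#' Atom coordinates with the role labelling needed for geometric
#' hydrogen-bond detection: donor heavy atoms, hydrogens linked to their
#' donor, acceptors, and a peptide/solvent segment flag.  The two tagged
#' end-to-end atoms define the pulled coordinate.
#'
#' @param atoms data.frame with columns \code{id}, \code{name},
#'   \code{element}, \code{resid}, \code{segment} ("PEP" or "SOL"),
#'   \code{role} ("donor", "hydrogen", "acceptor", "donor_acceptor",
#'   "other"), \code{x}, \code{y}, \code{z}
#' @param h_links data.frame with columns \code{hydrogen}, \code{donor}
#'   (atom ids); every hydrogen-role atom must appear exactly once
#' @param ee_tags named list of end-to-end tag pairs (atom id vectors of
#'   length 2); e.g. tags for the terminal backbone nitrogens and for the
#'   first/last alpha carbons
#' @return object of class \code{"structure_frame"}
#' @export
structure_frame <- function(atoms, h_links, ee_tags) {
  need <- c("id", "name", "element", "resid", "segment", "role",
            "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  if (any(atoms$resid < 1)) stop("residue indices must be >= 1")
  if (anyDuplicated(atoms$id)) stop("duplicate atom ids")
  hyd <- atoms$id[atoms$role == "hydrogen"]
  linked <- h_links$hydrogen
  if (!setequal(hyd, linked) || anyDuplicated(linked)) {
    stop("labelling error: every hydrogen must link to exactly one donor")
  }
  donor_roles <- atoms$role[match(h_links$donor, atoms$id)]
  if (any(!donor_roles %in% c("donor", "donor_acceptor"))) {
    stop("labelling error: hydrogen linked to a non-donor atom")
  }
  for (tag in ee_tags) {
    seg <- atoms$segment[match(tag, atoms$id)]
    if (length(tag) != 2L || any(is.na(seg)) || any(seg != "PEP")) {
      stop("end-to-end tags must reference two peptide atoms")
    }
  }
  structure(list(atoms = atoms, h_links = h_links, ee_tags = ee_tags),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> %d atoms (%d peptide, %d solvent), %d residues\n",
              nrow(x$atoms), sum(x$atoms$segment == "PEP"),
              sum(x$atoms$segment == "SOL"), length(unique(
                paste(x$atoms$segment, x$atoms$resid)))))
  invisible(x)
}

.frame_coords <- function(frame, ids = frame$atoms$id) {
  i <- match(ids, frame$atoms$id)
  as.matrix(frame$atoms[i, c("x", "y", "z")])
}

#' Ideal polyalanine-like backbone fixture
#'
#' Builds an N, H, CA, C, O backbone (five atoms per residue, no side
#' chains, no end caps) from the supplied phi/psi dihedrals with standard
#' bond lengths and angles, labels the N-H donors and C=O acceptors, and
#' tags both conventional end-to-end atom pairs (terminal nitrogens, and
#' first/last alpha carbons).
#'
#' Ideal alpha-helical dihedrals (phi = -57, psi = -47) produce the
#' canonical i -> i+4 hydrogen-bond ladder; the fully extended chain
#' (phi = psi = 180) has no intrapeptide hydrogen bonds.
#'
#' @param n_res number of residues (>= 2)
#' @param phi,psi backbone dihedrals [degrees]; scalars are recycled
#' @param omega peptide-bond dihedral [degrees], default 180 (trans)
#' @return a [structure_frame()]
#' @export
generate_helix_fixture <- function(n_res, phi = -57, psi = -47,
                                   omega = 180) {
  if (n_res < 2) stop("n_res must be >= 2")
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  g <- .geom
  # coordinates per residue: N, H, CA, C, O
  N <- CA <- C <- O <- H <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_NCA, 0, 0)
  th <- g$a_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + g$b_CAC * c(-cos(th), sin(th), 0)
  H[1, ] <- .place_atom(C[1, ], CA[1, ], N[1, ], g$b_NH, g$a_C_N_H, 180)
  for (i in seq_len(n_res - 1L)) {
    N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_CN,
                              g$a_CA_C_N, psi[i])
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_CO,
                          g$a_CA_C_O, psi[i] + 180)
    CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_NCA,
                               g$a_C_N_CA, omega)
    C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_CAC,
                              g$a_N_CA_C, phi[i + 1])
    H[i + 1, ] <- .place_atom(O[i, ], C[i, ], N[i + 1, ], g$b_NH,
                              g$a_C_N_H, 180)
  }
  O[n_res, ] <- .place_atom(N[n_res, ], CA[n_res, ], C[n_res, ], g$b_CO,
                            g$a_CA_C_O, psi[n_res] + 180)

  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    base <- (i - 1L) * 5L
    rows[[i]] <- data.frame(
      id = base + 1:5,
      name = c("N", "H", "CA", "C", "O"),
      element = c("N", "H", "C", "C", "O"),
      resid = i, segment = "PEP",
      role = c("donor", "hydrogen", "other", "other", "acceptor"),
      x = c(N[i, 1], H[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
      y = c(N[i, 2], H[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
      z = c(N[i, 3], H[i, 3], CA[i, 3], C[i, 3], O[i, 3]))
  }
  atoms <- do.call(rbind, rows)
  h_links <- data.frame(hydrogen = atoms$id[atoms$name == "H"],
                        donor = atoms$id[atoms$name == "N"])
  id_of <- function(name, res) atoms$id[atoms$name == name &
                                          atoms$resid == res]
  ee_tags <- list(N = c(id_of("N", 1L), id_of("N", n_res)),
                  CA = c(id_of("CA", 1L), id_of("CA", n_res)))
  structure_frame(atoms, h_links, ee_tags)
}

# run fn() under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# one pseudo-water: OW donor/acceptor plus two linked hydrogens
.water_atoms <- function(idx, resid, ow, h1, h2) {
  data.frame(
    id = idx + 0:2,
    name = c("OW", "HW1", "HW2"),
    element = c("O", "H", "H"),
    resid = resid, segment = "SOL",
    role = c("donor_acceptor", "hydrogen", "hydrogen"),
    x = c(ow[1], h1[1], h2[1]),
    y = c(ow[2], h1[2], h2[2]),
    z = c(ow[3], h1[3], h2[3]))
}

# any unit vector orthogonal to u
.perp <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(.cross3(u, ref))
}

#' Pseudo-solvated fixture for hydrogen-bond counting
#'
#' Appends \code{n_waters} three-site pseudo-waters to a peptide frame.
#' Exactly \code{hb_placed} of them are placed at ideal hydrogen-bonding
#' geometry to distinct peptide donors or acceptors (verified by detection
#' at construction time); all remaining waters are kept at least 6 A from
#' every peptide atom.  Deterministic given the seed; the caller's RNG
#' state is preserved.
#'
#' @param frame a peptide [structure_frame()]
#' @param n_waters total pseudo-waters to append
#' @param hb_placed number of waters placed as peptide-solvent hydrogen
#'   bonds (\code{<= n_waters})
#' @param seed integer seed controlling site choice and far-water placement
#' @param d_cut,angle_cut detection thresholds used for construction-time
#'   verification
#' @return a [structure_frame()] with the waters appended
#' @export
generate_solvated_fixture <- function(frame, n_waters, hb_placed, seed,
                                      d_cut = 4, angle_cut = 140) {
  stopifnot(inherits(frame, "structure_frame"))
  if (hb_placed > n_waters) stop("hb_placed must be <= n_waters")
  .with_seed(seed, function() {
    g <- .geom
    atoms <- frame$atoms
    pep <- atoms[atoms$segment == "PEP", ]
    pep_xyz <- as.matrix(pep[, c("x", "y", "z")])
    # candidate sites: peptide acceptors (water donates) and peptide
    # donor N-H pairs (water accepts)
    acc_ids <- pep$id[pep$role %in% c("acceptor", "donor_acceptor")]
    don <- frame$h_links[frame$h_links$donor %in% pep$id, ]
    sites <- rbind(
      if (length(acc_ids))
        data.frame(type = "acc", a1 = acc_ids, a2 = NA_integer_),
      if (nrow(don))
        data.frame(type = "don", a1 = don$donor, a2 = don$hydrogen))
    sites <- sites[sample.int(nrow(sites)), , drop = FALSE]

    coords_of <- function(id) {
      unlist(atoms[match(id, atoms$id), c("x", "y", "z")], use.names = FALSE)
    }
    next_id <- max(atoms$id) + 1L
    next_res <- max(atoms$resid) + 1L
    placed <- 0L
    out_atoms <- atoms
    out_links <- frame$h_links
    half <- g$a_HW_OW_HW / 2
    for (si in seq_len(nrow(sites))) {
      if (placed >= hb_placed) break
      s <- sites[si, ]
      if (s$type == "acc") {
        # water donates: OW along the C=O axis, one H pointing at O
        o <- coords_of(s$a1)
        res_o <- atoms$resid[match(s$a1, atoms$id)]
        cid <- atoms$id[atoms$resid == res_o & atoms$name == "C" &
                          atoms$segment == "PEP"]
        u <- if (length(cid) == 1L) .unit(o - coords_of(cid)) else c(0, 0, 1)
        ow <- o + 2.85 * u
        h1 <- ow - g$b_OW_HW * u
        v <- .perp(u)
        h2 <- ow + g$b_OW_HW *
          (cos(g$a_HW_OW_HW * pi / 180) * (-u) +
             sin(g$a_HW_OW_HW * pi / 180) * v)
      } else {
        # water accepts: OW on the N-H axis beyond H
        nN <- coords_of(s$a1)
        hH <- coords_of(s$a2)
        u <- .unit(hH - nN)
        ow <- nN + 2.85 * u
        v <- .perp(u)
        h1 <- ow + g$b_OW_HW * (cos(half * pi / 180) * u +
                                  sin(half * pi / 180) * v)
        h2 <- ow + g$b_OW_HW * (cos(half * pi / 180) * u -
                                  sin(half * pi / 180) * v)
      }
      # reject sites whose water would clash with or double-bond to the
      # peptide: verify by actual detection on peptide + this water
      dmin <- min(sqrt(rowSums((pep_xyz - matrix(ow, nrow(pep_xyz), 3,
                                                 byrow = TRUE))^2)))
      if (dmin < 2.4) next
      wat <- .water_atoms(next_id, next_res, ow, h1, h2)
      trial <- structure_frame(
        rbind(atoms, wat),
        rbind(frame$h_links,
              data.frame(hydrogen = wat$id[2:3], donor = wat$id[c(1, 1)])),
        frame$ee_tags)
      tb <- detect_hbonds(trial, d_cut = d_cut, angle_cut = angle_cut)
      cls <- classify_contacts(tb, trial)
      base <- classify_contacts(detect_hbonds(frame, d_cut, angle_cut),
                                frame)
      if (cls[["peptide_solvent"]] != 1L ||
          any(cls[names(cls) != "peptide_solvent"] !=
                base[names(base) != "peptide_solvent"])) next
      out_atoms <- rbind(out_atoms, wat)
      out_links <- rbind(out_links,
                         data.frame(hydrogen = wat$id[2:3],
                                    donor = wat$id[c(1, 1)]))
      next_id <- next_id + 3L
      next_res <- next_res + 1L
      placed <- placed + 1L
    }
    if (placed < hb_placed) {
      stop("insufficient accessible donor/acceptor sites: placed ", placed,
           " of ", hb_placed, " requested hydrogen-bonded waters")
    }
    # far waters: on a sphere well outside the peptide, mutually separated
    n_far <- n_waters - hb_placed
    if (n_far > 0L) {
      centre <- colMeans(pep_xyz)
      rad <- max(sqrt(rowSums((pep_xyz - matrix(centre, nrow(pep_xyz), 3,
                                                byrow = TRUE))^2)))
      far_pos <- list()
      attempts <- 0L
      while (length(far_pos) < n_far) {
        attempts <- attempts + 1L
        if (attempts > 10000L) stop("could not place distant waters")
        u <- .unit(rnorm(3))
        r <- rad + 8 + runif(1) * (4 + n_far)
        p <- centre + r * u
        ok <- all(vapply(far_pos, function(q) sqrt(sum((p - q)^2)) >= 5,
                         logical(1)))
        if (ok) far_pos[[length(far_pos) + 1L]] <- p
      }
      for (p in far_pos) {
        u <- .unit(rnorm(3))
        v <- .perp(u)
        h1 <- p + g$b_OW_HW * (cos(half * pi / 180) * u +
                                 sin(half * pi / 180) * v)
        h2 <- p + g$b_OW_HW * (cos(half * pi / 180) * u -
                                 sin(half * pi / 180) * v)
        wat <- .water_atoms(next_id, next_res, p, h1, h2)
        out_atoms <- rbind(out_atoms, wat)
        out_links <- rbind(out_links,
                           data.frame(hydrogen = wat$id[2:3],
                                      donor = wat$id[c(1, 1)]))
        next_id <- next_id + 3L
        next_res <- next_res + 1L
      }
    }
    rownames(out_atoms) <- NULL
    rownames(out_links) <- NULL
    structure_frame(out_atoms, out_links, frame$ee_tags)
  })
}

#' Write a structure frame as PDB plus a sidecar label table
#'
#' The occupancy column encodes the peptide/solvent flag (1.00 peptide,
#' 0.00 solvent); authoritative role labelling goes to a TSV sidecar
#' (\code{<path>.labels.tsv}) with columns atom_id, role, donor (linked
#' donor id for hydrogens), resid, segment.
#'
#' @param frame a [structure_frame()]
#' @param path output PDB path
#' @return invisibly, the paths written
#' @export
write_pdb <- function(frame, path) {
  a <- frame$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$id, substr(a$name, 1, 4), ifelse(a$segment == "PEP", "ALA", "HOH"),
    a$resid, a$x, a$y, a$z, ifelse(a$segment == "PEP", 1, 0), 0,
    a$element)
  writeLines(c(lines, "END"), path)
  lab_path <- paste0(path, ".labels.tsv")
  don <- frame$h_links$donor[match(a$id, frame$h_links$hydrogen)]
  lab <- data.frame(atom_id = a$id, role = a$role,
                    donor = ifelse(is.na(don), "", don),
                    resid = a$resid, segment = a$segment)
  ee <- vapply(frame$ee_tags, paste, character(1), collapse = ",")
  hdr <- sprintf("# ee_tag %s %s", names(frame$ee_tags), ee)
  writeLines(c(hdr, paste(names(lab), collapse = "\t"),
               do.call(paste, c(lab, sep = "\t"))), lab_path)
  invisible(c(path, lab_path))
}

#' Read a structure frame written by [write_pdb()]
#'
#' @param path PDB path; the \code{<path>.labels.tsv} sidecar must exist
#' @return a [structure_frame()]
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- lines[startsWith(lines, "ATOM")]
  atoms <- data.frame(
    id = as.integer(substr(rec, 7, 11)),
    name = trimws(substr(rec, 13, 16)),
    element = trimws(substr(rec, 77, 78)),
    resid = as.integer(substr(rec, 23, 26)),
    segment = ifelse(as.numeric(substr(rec, 55, 60)) >= 0.5, "PEP", "SOL"),
    role = NA_character_,
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)))
  lab_path <- paste0(path, ".labels.tsv")
  if (!file.exists(lab_path)) stop("label sidecar not found: ", lab_path)
  lab_lines <- readLines(lab_path)
  hdr <- lab_lines[startsWith(lab_lines, "# ee_tag")]
  lab <- read.table(text = lab_lines[!startsWith(lab_lines, "#")],
                    header = TRUE, sep = "\t",
                    colClasses = c("integer", "character", "character",
                                   "integer", "character"))
  i <- match(atoms$id, lab$atom_id)
  atoms$role <- lab$role[i]
  atoms$resid <- lab$resid[i]
  atoms$segment <- lab$segment[i]
  hy <- lab$atom_id[lab$role == "hydrogen"]
  h_links <- data.frame(hydrogen = hy,
                        donor = as.integer(lab$donor[match(hy,
                                                           lab$atom_id)]))
  ee_tags <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^# ee_tag ", "", h), " ")[[1]]
    ee_tags[[parts[1]]] <- as.integer(strsplit(parts[2], ",")[[1]])
  }
  structure_frame(atoms, h_links, ee_tags)
}
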