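# EVB topology for water protolysis: per-state atom types/charges, Morse
# bonds, harmonic angles, sqrt-form Lennard-Jones, Buckingham reactive
# repulsion, flat-bottom and positional restraints, droplet confinement.

#' EVB atom-type parameter table for water protolysis
#'
#' Per-type atomic charges (e), Lennard-Jones parameters stored as the
#' square roots of the standard A (kcal/mol Angstrom^12) and B (kcal/mol
#' Angstrom^6) coefficients (geometric combining: \eqn{A_{ij} =
#' \sqrt{A_i}\sqrt{A_j}}), and Buckingham repulsion constants C (kcal/mol)
#' and beta (1/Angstrom) for atoms involved in breaking/forming bonds.
#' Types: \code{ohh} water, \code{wpp} hydronium, \code{oh-} hydroxide,
#' \code{Na+} sodium.  All values in AKMA units.
#'
#' @return data frame with columns type, charge, sqrt_a, sqrt_b, buck_c,
#'   buck_beta.
#' @examples
#' evb_atom_types()
#' @export
evb_atom_types <- function() {
  data.frame(
    type      = c("ohh.O", "ohh.H", "wpp.O", "wpp.H", "oh-.O", "oh-.H", "Na+"),
    charge    = c(-0.80, 0.40, -0.08, 0.36, -1.01, 0.01, 1.00),
    sqrt_a    = c(762.8900, 6.2400, 762.8900, 6.2400, 976.9297, 69.5797, 143.6955),
    sqrt_b    = c(24.3900, 1.4700, 24.3900, 1.4700, 31.2559, 4.9095, 3.8899),
    buck_c    = c(20, 50, NA, 50, 20, NA, NA),
    buck_beta = c(1.58, 1.58, NA, 1.58, 1.58, NA, NA),
    stringsAsFactors = FALSE
  )
}

## package-chosen bonded parameters (AKMA); see the methods vignette
.morse_water     <- list(d_e = 102.9, beta = 2.287, r0 = 0.9572)
.morse_hydronium <- list(d_e = 102.9, beta = 2.287, r0 = 0.9820)
.morse_hydroxide <- list(d_e = 102.9, beta = 2.287, r0 = 0.9572)
## angle energy convention: E = k (theta - theta0)^2, k in kcal/mol/rad^2
.angle_water     <- list(k = 37.95, theta0 = 104.52)
.angle_hydronium <- list(k = 35.00, theta0 = 111.60)

.type_row <- function(type) {
  tt <- evb_atom_types()
  tt[match(type, tt$type), , drop = FALSE]
}

#' Construct the two-state protolysis topology for a droplet of n waters
#'
#' Atoms are ordered donor water (O1, H* transferring, H1b), acceptor water
#' (O2, H2a, H2b), then solvent waters (O, H, H).  In the reactant state
#' all molecules are flexible EVB waters; in the product state the donor
#' becomes hydroxide (O1-H1b) and the acceptor hydronium (O2 with three
#' hydrogens including H*).  The transferring hydrogen's bond appears in
#' exactly one state's bond list; Buckingham repulsion is applied to the
#' (H*, O1) and (H*, O2) pairs in both states, replacing their LJ term.
#' The two reactive oxygens carry a flat-bottom distance restraint
#' (2.5-3.5 Angstrom, 10 kcal/mol/Angstrom^2) and weak positional
#' restraints; all oxygens feel a half-harmonic spherical confinement.
#'
#' @param n_waters total number of water molecules (>= 2).
#' @param radius droplet confinement radius in Angstrom.
#' @param positions optional (n_waters x 3) matrix of oxygen positions used
#'   for the positional-restraint anchors of the reactive oxygens.
#' @param confinement_k confinement wall force constant
#'   (kcal/mol/Angstrom^2); default 10.
#' @param posres_k positional restraint on the two reactive oxygens
#'   (kcal/mol/Angstrom^2); default 0.5.
#' @param h_ij,alpha EVB coupling and gas-phase shift stored with the
#'   topology (used at analysis time); defaults 0.
#' @return an \code{"evb_topology"} object.
#' @seealso [build_droplet()], which packs coordinates and calls this.
#' @export
protolysis_topology <- function(n_waters, radius, positions = NULL,
                                confinement_k = 10, posres_k = 0.5,
                                h_ij = 0, alpha = 0) {
  stopifnot(n_waters >= 2, radius > 0)
  n_atoms <- 3L * n_waters
  o_idx <- seq(1L, n_atoms, by = 3L)
  tt <- function(type, col) .type_row(type)[[col]]

  atoms <- data.frame(
    id = seq_len(n_atoms),
    element = rep(c("O", "H", "H"), n_waters),
    type_reactant = rep(c("ohh.O", "ohh.H", "ohh.H"), n_waters),
    type_product = rep(c("ohh.O", "ohh.H", "ohh.H"), n_waters),
    stringsAsFactors = FALSE
  )
  ## product state: donor water -> hydroxide, acceptor water -> hydronium
  atoms$type_product[1] <- "oh-.O"   # O1
  atoms$type_product[2] <- "wpp.H"   # H*, moves to the hydronium
  atoms$type_product[3] <- "oh-.H"   # H1b stays on the hydroxide
  atoms$type_product[4] <- "wpp.O"   # O2
  atoms$type_product[5] <- "wpp.H"
  atoms$type_product[6] <- "wpp.H"
  att <- evb_atom_types()
  ir <- match(atoms$type_reactant, att$type)
  ip <- match(atoms$type_product, att$type)
  atoms$q_reactant <- att$charge[ir]
  atoms$q_product <- att$charge[ip]
  atoms$sqrt_a_reactant <- att$sqrt_a[ir]
  atoms$sqrt_b_reactant <- att$sqrt_b[ir]
  atoms$sqrt_a_product <- att$sqrt_a[ip]
  atoms$sqrt_b_product <- att$sqrt_b[ip]
  atoms$mass <- ifelse(atoms$element == "O", 15.999, 1.008)

  mw <- .morse_water; mh <- .morse_hydronium; mx <- .morse_hydroxide
  bonds <- data.frame(
    i = integer(), j = integer(), d_e = numeric(), beta = numeric(),
    r0 = numeric(), state = character(), stringsAsFactors = FALSE)
  addb <- function(b, i, j, p, state)
    rbind(b, data.frame(i = i, j = j, d_e = p$d_e, beta = p$beta, r0 = p$r0,
                        state = state, stringsAsFactors = FALSE))
  ## donor water / hydroxide
  bonds <- addb(bonds, 1L, 2L, mw, "reactant")      # O1-H*, broken in product
  bonds <- addb(bonds, 1L, 3L, mw, "reactant")
  bonds <- addb(bonds, 1L, 3L, mx, "product")
  ## acceptor water / hydronium
  bonds <- addb(bonds, 4L, 5L, mw, "reactant")
  bonds <- addb(bonds, 4L, 6L, mw, "reactant")
  bonds <- addb(bonds, 4L, 5L, mh, "product")
  bonds <- addb(bonds, 4L, 6L, mh, "product")
  bonds <- addb(bonds, 4L, 2L, mh, "product")       # O2-H*, formed
  ## solvent waters
  for (w in seq_len(n_waters - 2L)) {
    o <- 6L + 3L * (w - 1L) + 1L
    bonds <- addb(bonds, o, o + 1L, mw, "both")
    bonds <- addb(bonds, o, o + 2L, mw, "both")
  }

  aw <- .angle_water; ah <- .angle_hydronium
  angles <- data.frame(
    i = integer(), j = integer(), k = integer(), force_constant = numeric(),
    theta0 = numeric(), state = character(), stringsAsFactors = FALSE)
  adda <- function(a, i, j, k, p, state)
    rbind(a, data.frame(i = i, j = j, k = k, force_constant = p$k,
                        theta0 = p$theta0, state = state,
                        stringsAsFactors = FALSE))
  angles <- adda(angles, 2L, 1L, 3L, aw, "reactant")  # donor water
  angles <- adda(angles, 5L, 4L, 6L, aw, "reactant")  # acceptor water
  angles <- adda(angles, 5L, 4L, 6L, ah, "product")   # hydronium
  angles <- adda(angles, 5L, 4L, 2L, ah, "product")
  angles <- adda(angles, 6L, 4L, 2L, ah, "product")
  for (w in seq_len(n_waters - 2L)) {
    o <- 6L + 3L * (w - 1L) + 1L
    angles <- adda(angles, o + 1L, o, o + 2L, aw, "both")
  }

  buck_c <- sqrt(tt("ohh.H", "buck_c") * tt("ohh.O", "buck_c"))  # geometric
  buckingham <- data.frame(i = c(2L, 2L), j = c(1L, 4L),
                           c = buck_c, beta = 1.58)

  restraints <- data.frame(i = 1L, j = 4L, lower = 2.5, upper = 3.5,
                           force_constant = 10)
  posres <- if (posres_k > 0 && !is.null(positions)) {
    data.frame(atom = c(1L, 4L),
               x = positions[c(1, 4), 1], y = positions[c(1, 4), 2],
               z = positions[c(1, 4), 3], force_constant = posres_k)
  } else {
    data.frame(atom = integer(), x = numeric(), y = numeric(), z = numeric(),
               force_constant = numeric())
  }

  topo <- list(
    atoms = atoms, bonds = bonds, angles = angles, buckingham = buckingham,
    restraints = restraints, posres = posres,
    confinement = list(atoms = o_idx, radius = radius,
                       force_constant = confinement_k, center = c(0, 0, 0)),
    evb_region = 1:6,
    coupling = list(h_ij = h_ij, alpha = alpha),
    net_charge = c(reactant = 0, product = 0)
  )
  class(topo) <- "evb_topology"
  validate_topology(topo)
  topo
}

#' Validate an EVB topology
#'
#' Checks the structural invariants: reactive (single-state) bonds appear in
#' exactly one state's bond list, per-state charge sums match the declared
#' net charges, restraint bounds are ordered, and all parameters are finite.
#'
#' @param topology an \code{"evb_topology"}.
#' @return the topology, invisibly; errors describe the first violation.
#' @export
validate_topology <- function(topology) {
  stopifnot(inherits(topology, "evb_topology"))
  a <- topology$atoms
  if (!all(is.finite(c(a$q_reactant, a$q_product))))
    stop("atomic charges must be finite")
  for (s in c("reactant", "product")) {
    qs <- sum(a[[paste0("q_", s)]])
    if (abs(qs - topology$net_charge[[s]]) > 1e-6)
      stop("charge sum in ", s, " state (", qs, ") does not match declared ",
           "net charge (", topology$net_charge[[s]], ")")
  }
  b <- topology$bonds
  if (nrow(b)) {
    if (!all(b$state %in% c("both", "reactant", "product")))
      stop("bond 'state' must be both/reactant/product")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    for (kk in unique(key[b$state != "both"])) {
      st <- b$state[key == kk]
      if (any(st == "both") || anyDuplicated(st))
        stop("reactive bond ", kk, " must appear in exactly one state's list")
    }
    if (!all(b$d_e > 0 & b$beta > 0 & b$r0 > 0))
      stop("Morse parameters must be positive")
  }
  r <- topology$restraints
  if (nrow(r) && !all(r$lower < r$upper & r$force_constant >= 0))
    stop("flat-bottom restraints need lower < upper and k >= 0")
  invisible(topology)
}

## rows of a state-tagged table active in a given state
.state_rows <- function(df, state) df[df$state %in% c("both", state), , drop = FALSE]

## 1-2 and 1-3 exclusion keys for one state's bond graph
.exclusion_keys <- function(bonds, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  keys <- character(0)
  pkey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  for (r in seq_len(nrow(bonds)))
    keys <- c(keys, pkey(bonds$i[r], bonds$j[r]))
  for (a in seq_len(n)) {
    nb <- adj[[a]]
    if (length(nb) > 1) {
      cmb <- utils::combn(nb, 2)
      keys <- c(keys, pkey(cmb[1, ], cmb[2, ]))
    }
  }
  unique(keys)
}

## assemble flat numeric structures for the compiled engine (0-based indices)
.prepare_engine <- function(topology) {
  validate_topology(topology)
  a <- topology$atoms
  n <- nrow(a)
  ij <- utils::combn(n, 2)
  pkey <- paste(ij[1, ], ij[2, ])
  bkey <- paste(pmin(topology$buckingham$i, topology$buckingham$j),
                pmax(topology$buckingham$i, topology$buckingham$j))
  state_pairs <- function(state) {
    b <- .state_rows(topology$bonds, state)
    excl <- .exclusion_keys(b, n)
    keep <- !(pkey %in% excl)
    i <- ij[1, keep]; j <- ij[2, keep]
    q <- a[[paste0("q_", state)]]
    sa <- a[[paste0("sqrt_a_", state)]]
    sb <- a[[paste0("sqrt_b_", state)]]
    A <- sa[i] * sa[j]
    B <- sb[i] * sb[j]
    ## reactive pairs: LJ replaced by Buckingham; keep a small r^-12 core
    ## (2 kcal A^12, < 0.25 kcal/mol beyond 1.2 A) so the exponential
    ## repulsion cannot be overwhelmed by the Coulomb singularity
    no_lj <- paste(i, j) %in% bkey
    A[no_lj] <- 2; B[no_lj] <- 0
    cbind(i = i - 1, j = j - 1, qq = .ke * q[i] * q[j], A = A, B = B)
  }
  state_bonds <- function(state) {
    b <- .state_rows(topology$bonds, state)
    cbind(i = b$i - 1, j = b$j - 1, D = b$d_e, beta = b$beta, r0 = b$r0)
  }
  state_angles <- function(state) {
    g <- .state_rows(topology$angles, state)
    cbind(i = g$i - 1, j = g$j - 1, k = g$k - 1, kth = g$force_constant,
          th0 = g$theta0 * pi / 180)
  }
  bu <- topology$buckingham
  re <- topology$restraints
  pr <- topology$posres
  cf <- topology$confinement
  list(
    n = n, mass = a$mass,
    pairs1 = state_pairs("reactant"), pairs2 = state_pairs("product"),
    bonds1 = state_bonds("reactant"), bonds2 = state_bonds("product"),
    angles1 = state_angles("reactant"), angles2 = state_angles("product"),
    buck = cbind(i = bu$i - 1, j = bu$j - 1, C = bu$c, beta = bu$beta),
    restraints = cbind(i = re$i - 1, j = re$j - 1, lower = re$lower,
                       upper = re$upper, k = re$force_constant),
    posres = cbind(i = pr$atom - 1, x = pr$x, y = pr$y, z = pr$z,
                   k = pr$force_constant),
    confine_atoms = cf$atoms - 1,
    confine_radius = cf$radius, confine_k = cf$force_constant,
    confine_center = cf$center
  )
}

#' Write an EVB topology to a declarative YAML file
#'
#' Serializes the full topology (atom types and per-state charges/LJ, Morse
#' bonds, angles, Buckingham pairs, restraints, confinement, coupling) in a
#' YAML dialect mirroring the parameter-table structure.
#'
#' @param topology an \code{"evb_topology"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "evb_topology"))
  obj <- list(
    atoms = lapply(seq_len(nrow(topology$atoms)), function(i)
      as.list(topology$atoms[i, ])),
    bonds = lapply(seq_len(nrow(topology$bonds)), function(i)
      as.list(topology$bonds[i, ])),
    angles = lapply(seq_len(nrow(topology$angles)), function(i)
      as.list(topology$angles[i, ])),
    buckingham = lapply(seq_len(nrow(topology$buckingham)), function(i)
      as.list(topology$buckingham[i, ])),
    restraints = lapply(seq_len(nrow(topology$restraints)), function(i)
      as.list(topology$restraints[i, ])),
    posres = lapply(seq_len(nrow(topology$posres)), function(i)
      as.list(topology$posres[i, ])),
    confinement = topology$confinement,
    evb_region = topology$evb_region,
    coupling = topology$coupling,
    net_charge = as.list(topology$net_charge)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read an EVB topology from a YAML file
#'
#' @param path path to a file written by [write_topology()].
#' @return an \code{"evb_topology"}.
#' @export
read_topology <- function(path) {
  obj <- yaml::read_yaml(path)
  todf <- function(x) do.call(rbind, lapply(x, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  empty <- function(proto) proto[0, , drop = FALSE]
  topo <- list(
    atoms = todf(obj$atoms),
    bonds = if (length(obj$bonds)) todf(obj$bonds) else
      data.frame(i = integer(), j = integer(), d_e = numeric(),
                 beta = numeric(), r0 = numeric(), state = character()),
    angles = if (length(obj$angles)) todf(obj$angles) else
      data.frame(i = integer(), j = integer(), k = integer(),
                 force_constant = numeric(), theta0 = numeric(),
                 state = character()),
    buckingham = if (length(obj$buckingham)) todf(obj$buckingham) else
      data.frame(i = integer(), j = integer(), c = numeric(), beta = numeric()),
    restraints = if (length(obj$restraints)) todf(obj$restraints) else
      data.frame(i = integer(), j = integer(), lower = numeric(),
                 upper = numeric(), force_constant = numeric()),
    posres = if (length(obj$posres)) todf(obj$posres) else
      data.frame(atom = integer(), x = numeric(), y = numeric(),
                 z = numeric(), force_constant = numeric()),
    confinement = list(atoms = as.integer(obj$confinement$atoms),
                       radius = obj$confinement$radius,
                       force_constant = obj$confinement$force_constant,
                       center = as.numeric(obj$confinement$center)),
    evb_region = as.integer(obj$evb_region),
    coupling = obj$coupling,
    net_charge = unlist(obj$net_charge)
  )
  class(topo) <- "evb_topology"
  validate_topology(topo)
  topo
}

#' @export
print.evb_topology <- function(x, ...) {
  cat(sprintf("EVB topology: %d atoms, %d bonds, %d angles, %d Buckingham pairs\n",
              nrow(x$atoms), nrow(x$bonds), nrow(x$angles), nrow(x$buckingham)))
  cat(sprintf("  EVB region: atoms %s\n", paste(range(x$evb_region), collapse = "-")))
  cat(sprintf("  coupling: H_ij = %.4g, alpha = %.4g kcal/mol\n",
              x$coupling$h_ij, x$coupling$alpha))
  invisible(x)
}
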