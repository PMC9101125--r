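#' Fluoro/hydroxy furanose test set
#'
#' Builds the package's set of 24 synthetic furanose ring templates used to
#' exercise the parameterization workflow.  Each template is a
#' tetrahydrofuran ring (C1'-C4', O4') carrying a 1'-methoxy group (so the
#' ether-oxygen atom type os appears next to the ring), a 4'-hydroxymethyl
#' arm (C5'-O5'H), and one of 24 combinations of fluoro/hydroxy substitution
#' at the 2' and 3' positions covering mono-, di- and gem-substitution on
#' either ring face.  Atom types follow GAFF conventions (c3, os, oh, ho,
#' f, h1); partial charges are simple electronegativity-motivated values
#' balanced to a net charge of zero.  These are synthetic stand-ins
#' constructed in code, not literature geometries.
#'
#' @param i template number 1..24.
#' @return `furanose_template()` returns one `molecular_template`;
#'   `furanose_templates()` returns the list of all 24.
#' @examples
#' t1 <- furanose_template(1)
#' t1
#' @export
furanose_template <- function(i) {
  stopifnot(i >= 1, i <= 24)
  combos <- furanose_substituent_combos()
  build_furanose(sprintf("T%02d", i), combos[[i]]$c2, combos[[i]]$c3)
}

#' @rdname furanose_template
#' @export
furanose_templates <- function() {
  lapply(1:24, furanose_template)
}

## 6 substitution patterns at C2' x 4 at C3' = 24 templates.
## Each entry is c(up-face substituent, down-face substituent).
furanose_substituent_combos <- function() {
  s2 <- list(c("F", "H"), c("H", "F"), c("OH", "H"),
             c("H", "OH"), c("F", "F"), c("F", "OH"))
  s3 <- list(c("F", "H"), c("H", "F"), c("OH", "H"), c("H", "OH"))
  out <- list()
  for (a in s2) for (b in s3) out[[length(out) + 1]] <- list(c2 = a, c3 = b)
  out
}

## Geometry helper: unit vector.
unitv <- function(v) v / sqrt(sum(v^2))

build_furanose <- function(id, sub2, sub3) {
  # ring: planar pentagon, side 1.50 A, order C1' C2' C3' C4' O4'
  side <- 1.50
  r <- side / (2 * sin(36 * DEG))
  ang <- (90 - 72 * (0:4)) * DEG
  ring_xyz <- cbind(r * cos(ang), r * sin(ang), 0)

  env <- new.env()
  env$atoms <- data.frame(name = character(), element = character(),
                          type = character(), charge = numeric(),
                          x = numeric(), y = numeric(), z = numeric(),
                          stringsAsFactors = FALSE)
  env$bonds <- matrix(integer(0), ncol = 2)
  add_atom <- function(name, element, type, pos, bond_to = NULL) {
    pos <- as.numeric(pos)
    env$atoms <- rbind(env$atoms, data.frame(
      name = name, element = element, type = type, charge = 0,
      x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE))
    idx <- nrow(env$atoms)
    if (!is.null(bond_to))
      env$bonds <- rbind(env$bonds, c(bond_to, idx))
    idx
  }

  ring_names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  ring_types <- c("c3", "c3", "c3", "c3", "os")
  ring_elem <- c("C", "C", "C", "C", "O")
  ring_idx <- integer(5)
  for (k in 1:5)
    ring_idx[k] <- add_atom(ring_names[k], ring_elem[k], ring_types[k],
                            ring_xyz[k, ])
  for (k in 1:5)
    env$bonds <- rbind(env$bonds, c(ring_idx[k], ring_idx[c(2:5, 1)[k]]))

  # substituent directions above/below the ring plane at each carbon
  centroid <- colMeans(ring_xyz)
  subst_dirs <- function(k) {
    u <- unitv(ring_xyz[k, ] - centroid)
    list(up = unitv(0.55 * u + c(0, 0, 0.84)),
         dn = unitv(0.55 * u - c(0, 0, 0.84)))
  }
  blen <- c(H = 1.09, F = 1.35, O = 1.43)

  attach_simple <- function(k, what, tag) {
    d <- subst_dirs(k)
    anchor <- ring_idx[k]
    for (face in c("up", "dn")) {
      s <- if (face == "up") what[1] else what[2]
      dir <- d[[face]]
      base <- ring_xyz[k, ]
      if (s == "H") {
        add_atom(paste0("H", tag, face), "H", "h1", base + blen["H"] * dir, anchor)
      } else if (s == "F") {
        add_atom(paste0("F", tag, face), "F", "f", base + blen["F"] * dir, anchor)
      } else if (s == "OH") {
        o <- add_atom(paste0("O", tag, face), "O", "oh", base + blen["O"] * dir,
                      anchor)
        lat <- unitv(dir + 0.9 * unitv(c(-dir[2], dir[1], 0.15)))
        add_atom(paste0("HO", tag, face), "H", "ho",
                 base + blen["O"] * dir + 0.97 * lat, o)
      }
    }
  }

  # C1': methoxy up, H down
  d1 <- subst_dirs(1)
  o_me <- add_atom("O1M", "O", "os", ring_xyz[1, ] + 1.43 * d1$up, ring_idx[1])
  me_dir <- unitv(d1$up + c(0.9, 0.25, 0.1))
  c_me_pos <- ring_xyz[1, ] + 1.43 * d1$up + 1.43 * me_dir
  c_me <- add_atom("C1M", "C", "c3", c_me_pos, o_me)
  for (j in 1:3) {
    hd <- unitv(me_dir + 1.2 * rotation_matrix(me_dir, 2 * pi * j / 3) %*%
                  unitv(c(-me_dir[2], me_dir[1], 0.4)))
    add_atom(paste0("H1M", j), "H", "h1", c_me_pos + 1.09 * hd, c_me)
  }
  add_atom("H1'", "H", "h1", ring_xyz[1, ] + 1.09 * d1$dn, ring_idx[1])

  # C2', C3': requested substitution patterns
  attach_simple(2, sub2, "2")
  attach_simple(3, sub3, "3")

  # C4': hydroxymethyl up, H down
  d4 <- subst_dirs(4)
  c5_pos <- ring_xyz[4, ] + 1.53 * d4$up
  c5 <- add_atom("C5'", "C", "c3", c5_pos, ring_idx[4])
  arm <- unitv(d4$up + c(-0.8, 0.35, 0.2))
  o5_pos <- c5_pos + 1.43 * arm
  o5 <- add_atom("O5'", "O", "oh", o5_pos, c5)
  add_atom("HO5'", "H", "ho",
           o5_pos + 0.97 * unitv(arm + 0.9 * unitv(c(-arm[2], arm[1], 0.3))), o5)
  for (j in 1:2) {
    hd <- unitv(d4$up + 1.3 * rotation_matrix(d4$up, pi / 2 + pi * j) %*%
                  unitv(c(-arm[2], arm[1], 0.5)))
    add_atom(paste0("H5'", j), "H", "h1", c5_pos + 1.09 * hd, c5)
  }
  add_atom("H4'", "H", "h1", ring_xyz[4, ] + 1.09 * d4$dn, ring_idx[4])

  # simple balanced charge model: fixed values on heteroatoms/hydrogens,
  # the residual spread over the carbons, exact to 6 decimals
  at <- env$atoms
  q <- numeric(nrow(at))
  q[at$type == "f"] <- -0.22
  q[at$type == "oh"] <- -0.60
  q[at$type == "ho"] <- 0.42
  q[at$type == "os"] <- -0.40
  q[at$type == "h1"] <- 0.06
  carbons <- which(at$type == "c3")
  # 4 decimals: the precision of the mol2 charge column, so templates
  # round-trip exactly through file I/O
  q[carbons] <- -sum(q) / length(carbons)
  q <- round(q, 4)
  q[carbons[1]] <- q[carbons[1]] - sum(q)
  env$atoms$charge <- q

  molecular_template(env$atoms, env$bonds, net_charge = 0,
                     ring = ring_idx, id = id)
}
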