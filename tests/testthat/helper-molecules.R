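# Small molecule fixtures built in code. Ring coordinates are idealized
# regular polygons; perception uses graph topology for ring membership and
# coordinates only for centroids, so idealized geometry is exact for tests.

hexagon_coords <- function(r = 1.39, center = c(0, 0, 0)) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  sweep(cbind(r * cos(ang), r * sin(ang), 0), 2, -center)
}

make_benzene <- function(center = c(0, 0, 0), mol_id = "benzene") {
  molecule3d(mol_id, 0L,
             atoms = data.frame(element = rep("C", 6)),
             bonds = data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
             coords = hexagon_coords(center = center))
}

make_pyridine <- function(center = c(0, 0, 0)) {
  molecule3d("pyridine", 0L,
             atoms = data.frame(element = c("N", rep("C", 5))),
             bonds = data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
             coords = hexagon_coords(center = center))
}

make_butane <- function() {
  molecule3d("butane", 0L,
             atoms = data.frame(element = rep("C", 4)),
             bonds = data.frame(i = 1:3, j = 2:4, order = 1L),
             coords = cbind(c(0, 1.5, 3.0, 4.5), c(0, 0.6, 0, 0.6), 0))
}

# bicyclic indole: pyrrole (atoms 1-5, N1 with explicit H at atom 10)
# fused to benzene (atoms 4-9) along the 4-5 bond
make_indole <- function() {
  coords <- rbind(
    c(0.00, 1.30, 0), c(1.25, 0.85, 0), c(1.25, -0.55, 0),
    c(0.00, -1.00, 0), c(-0.80, 0.15, 0),
    c(-2.20, 0.15, 0), c(-2.95, -1.00, 0), c(-2.20, -2.15, 0),
    c(-0.80, -2.15, 0), c(0.45, 2.25, 0))
  molecule3d("indole", 0L,
             atoms = data.frame(
               element = c("N", rep("C", 8), "H")),
             bonds = data.frame(
               i = c(1, 2, 3, 4, 5, 5, 6, 7, 8, 9, 1),
               j = c(2, 3, 4, 5, 1, 6, 7, 8, 9, 4, 10),
               order = c(4, 4, 4, 4, 4, 4, 4, 4, 4, 4, 1)),
             coords = coords)
}

# secondary amide H-N-C(=O)-C: donor NH + carbonyl acceptor O
make_amide <- function(origin = c(0, 0, 0)) {
  coords <- sweep(rbind(c(0, 0, 0), c(-0.9, 0.6, 0), c(1.3, 0.4, 0),
                        c(2.0, 1.4, 0), c(1.9, -0.9, 0)), 2, -origin)
  molecule3d("amide", 0L,
             atoms = data.frame(element = c("N", "H", "C", "O", "C")),
             bonds = data.frame(i = c(1, 1, 3, 3), j = c(2, 3, 4, 5),
                                order = c(1, 1, 2, 1)),
             coords = coords)
}

# disconnected multi-fragment scaffold mimicking the hit chemotype:
# indole + 3,5-dimethylphenyl + pyridine + two amide NH groups
make_hit_scaffold <- function() {
  ind <- make_indole()
  pyr <- make_pyridine(center = c(8, 0, 0))
  am1 <- make_amide(origin = c(0, 8, 0))
  am2 <- make_amide(origin = c(8, 8, 0))
  # 3,5-dimethylphenyl: benzene at (16,0,0) with methyls on atoms 1 and 3
  hx <- hexagon_coords(center = c(16, 0, 0))
  me <- rbind(hx[1, ] + c(1.5, 0, 0), hx[3, ] + c(-0.9, 1.2, 0))
  dmp <- molecule3d("dmp", 0L,
                    atoms = data.frame(element = rep("C", 8)),
                    bonds = data.frame(i = c(1:6, 1, 3),
                                       j = c(2:6, 1, 7, 8),
                                       order = c(rep(4L, 6), 1L, 1L)),
                    coords = rbind(hx, me))
  frags <- list(ind, dmp, pyr, am1, am2)
  atoms <- do.call(rbind, lapply(frags, function(m) m$atoms))
  offs <- cumsum(c(0L, vapply(frags, n_atoms, 0L)))[1:5]
  bonds <- do.call(rbind, Map(function(m, o) {
    data.frame(i = m$bonds$i + o, j = m$bonds$j + o, order = m$bonds$order)
  }, frags, offs))
  coords <- do.call(rbind, lapply(frags, function(m) m$coords))
  molecule3d("hit_scaffold", 0L, atoms, bonds, coords)
}

# a feature table placed exactly at the model's query positions
perfect_features <- function(model) {
  q <- model$queries
  data.frame(kind = q$kind, x = q$x, y = q$y, z = q$z,
             stringsAsFactors = FALSE)
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
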