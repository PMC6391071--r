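## Shared helpers: tiny atom-record builders and rotation matrices.

atomRow <- function(x, y, z, chain = "A", resno = 1, atom = "CA",
                    element = "C", resid = "GLY", occupancy = 1) {
  data.frame(chain = chain, resno = resno, resid = resid, atom = atom,
             element = element, x = x, y = y, z = z, occupancy = occupancy,
             stringsAsFactors = FALSE)
}

rotZ <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

rotX <- function(deg) {
  th <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
}

## apply a rigid motion to the coordinate columns of an atom data.frame
moveAtoms <- function(sel, R = diag(3), t = c(0, 0, 0)) {
  p <- as.matrix(sel[, c("x", "y", "z")]) %*% t(R)
  sel$x <- p[, 1] + t[1]; sel$y <- p[, 2] + t[2]; sel$z <- p[, 3] + t[3]
  sel
}

## a small standard assembly used across tests
standardAssembly <- function(seed = 2, ...)
  makeAssembly(AssemblyParams(6, 4.1, 56.4, 30, seed = seed, ...))
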