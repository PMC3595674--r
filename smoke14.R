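library(mreit)
# segment_domain: ellipse support area
g <- slice_grid(128, 128, dx = 1.4e-3)
xy <- mreit:::grid_xy(g); ctr <- mreit:::grid_center(g)
half <- c((g$nx-1)*g$dx/2,(g$ny-1)*g$dy/2)
a <- 0.6*half[1]; b <- 0.4*half[2]
M <- ifelse(((xy$x-ctr[1])/a)^2 + ((xy$y-ctr[2])/b)^2 <= 1, 100, 0)
poly <- segment_domain(M, g)
cat("area rel err:", abs(polygon_area(poly) - pi*a*b)/(pi*a*b), "\n")
# full frame constant
polyf <- segment_domain(matrix(5, 16, 16), slice_grid(16, 16, dx=1e-3))
print(polyf)
# attach electrodes quarter arcs on circle
th <- seq(0, 2*pi, length.out = 129)[-129]
circ <- cbind(cos(th), sin(th))
cp <- mreit:::new_domain_polygon(circ)
spec <- data.frame(injection=c(1,1,2,2), polarity=c(1,-1,1,-1),
                   angle=c(0, pi, pi/2, 3*pi/2), length=rep(cp$perimeter/4 * 0.98, 4))
cpe <- attach_electrodes(cp, spec)
print(cpe$arcs)
# triangulate unit square
sq <- mreit:::new_domain_polygon(rbind(c(0,0), c(1,0), c(1,1), c(0,1)))
msq <- triangulate_domain(sq, max_area = 0.005)
cat("n tri:", nrow(msq$triangles), "max area:", max(msq$area), "sum:", sum(msq$area), "\n")
# mesh from polygon w/ markers + forward FD oracle at 64
g2 <- slice_grid(64, 64, dx = 2.8e-3)
ell <- data.frame(cx=c(0,-0.2,0.25), cy=c(0,0.1,-0.15), a=c(0.8,0.25,0.2), b=c(0.9,0.3,0.25),
                  angle=c(0,0,0), value=c(1,2,0.5))
ph <- make_shepp_logan(g2, ell)
el <- electrode_config()
mesh <- mesh_from_mask(g2, ph$domain_mask, el)
p1 <- solve_forward_2d(ph, el, 1, mesh = mesh)
# FD oracle: 5-point var coef with harmonic mean faces, Dirichlet on electrode pixels
fd_solve <- function(sigma, mask, dirpix, dirval) {
  ny <- nrow(mask); nx <- ncol(mask)
  idx <- matrix(0L, ny, nx); un <- which(mask & !dirpix); idx[un] <- seq_along(un)
  n <- length(un)
  ii <- jj <- integer(0); vv <- numeric(0); b <- numeric(n); dg <- numeric(n)
  r <- ((un-1)%%ny)+1; c <- ((un-1)%/%ny)+1
  for (k in 1:4) {
    rr <- r + c(-1,1,0,0)[k]; cc <- c + c(0,0,-1,1)[k]
    inb <- rr>=1 & rr<=ny & cc>=1 & cc<=nx
    q <- ifelse(inb, (cc-1)*ny+rr, 1L)
    act <- inb & mask[q]
    w <- numeric(n)
    w[act] <- 2/(1/sigma[un[act]] + 1/sigma[q[act]])
    dg <- dg + w
    isu <- act & !dirpix[q]
    wme <- which(isu)
    ii <- c(ii, wme); jj <- c(jj, idx[q[wme]]); vv <- c(vv, -w[wme])
    isd <- act & dirpix[q]
    b[isd] <- b[isd] + w[isd]*dirval[q[isd]]
  }
  A <- Matrix::sparseMatrix(i=c(seq_len(n), ii), j=c(seq_len(n), jj), x=c(dg, vv), dims=c(n,n))
  x <- as.numeric(Matrix::solve(A, b))
  out <- matrix(NA_real_, ny, nx); out[un] <- x; out[dirpix] <- dirval[dirpix]
  out
}
# electrode pixels: boundary-ring pixels within arcs
ctr2 <- mreit:::mask_centroid(g2, ph$domain_mask)
xy2 <- mreit:::grid_xy(g2)
thp <- atan2(xy2$y - ctr2[2], xy2$x - ctr2[1])
ringp <- mreit:::boundary_ring(ph$domain_mask)
arcs <- el$arcs
dirpix <- matrix(FALSE, 64, 64); dirval <- matrix(0, 64, 64)
for (i in 1:2) {
  hit <- ringp & mreit:::angle_in_arc(thp, arcs$angle0[i], arcs$angle1[i])
  dirpix <- dirpix | hit
  dirval[hit] <- ifelse(arcs$polarity[i] > 0, 1, -1)
}
ufd <- fd_solve(ph$sigma, ph$domain_mask, dirpix, dirval)
ufem <- matrix(mreit:::eval_mesh(mesh, p1$u, as.numeric(xy2$x), as.numeric(xy2$y)), 64, 64)
ok <- is.finite(ufd) & is.finite(ufem) & ph$domain_mask
cat("FD-FEM rel L2:", sqrt(sum((ufd[ok]-ufem[ok])^2)/sum(ufem[ok]^2)), "\n")
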