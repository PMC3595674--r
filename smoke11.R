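library(mreit)
# inpaint: linear refill
f <- outer(1:20, 1:20, function(r, c) 0.3*c + 0.7*r)
hole <- matrix(FALSE, 20, 20); hole[8:12, 9:14] <- TRUE
rep1 <- harmonic_inpaint(f, hole)
cat("linear refill max err:", max(abs(rep1 - f)), "\n")

# local vs global A/B at 96x96
g <- slice_grid(96, 96, dx = 1.8e-3)
el <- electrode_config()
ell <- data.frame(cx=c(0,0.0), cy=c(0,0.25), a=c(0.78,0.2), b=c(0.92,0.2), angle=c(0,0), value=c(1,1.25))
case <- simulate_mreit(g, ellipses = ell, electrodes = el)
dm <- case$phantom$domain_mask
bzv <- case$bz_true
# corrupt a patch at bottom of the domain (outside D)
ctr <- mreit:::grid_center(g); half <- c((g$nx-1)*g$dx/2,(g$ny-1)*g$dy/2)
xy <- mreit:::grid_xy(g)
patch <- ((xy$x-ctr[1])/ (0.3*half[1]))^2 + ((xy$y-(ctr[2]-0.45*half[2]))/(0.3*half[2]))^2 <= 1
set.seed(7)
for (j in 1:2) {
  sl <- bzv$bz[,,1,j]
  sl[patch] <- sl[patch] + rnorm(sum(patch), sd = 0.5*diff(range(sl[dm])))
  bzv$bz[,,1,j] <- sl
}
ph0 <- case$phantom; ph0$sigma <- matrix(1, 96, 96)
pots0 <- lapply(1:2, function(j) solve_forward_2d(ph0, el, j, mesh = case$mesh))
Js0 <- lapply(pots0, function(p) current_density(ph0, p, el))
af <- build_a_matrix(Js0[[1]], Js0[[2]])
l1 <- laplacian_bz(bzv, 1, 1); l2 <- laplacian_bz(bzv, 1, 2)
recg <- harmonic_bz_reconstruct(case$mesh, af, l1, l2)
# local D: box around upper anomaly
D <- rbind(c(ctr[1]-0.5*half[1], ctr[2]-0.05*half[2]),
           c(ctr[1]+0.5*half[1], ctr[2]-0.05*half[2]),
           c(ctr[1]+0.5*half[1], ctr[2]+0.6*half[2]),
           c(ctr[1]-0.5*half[1], ctr[2]+0.6*half[2]))
Dp <- mreit:::new_domain_polygon(D)
recl <- local_harmonic_bz(Dp, af, l1, l2, g)
# compare lnsigma rasters on D pixels
inD <- matrix(pracma::inpolygon(as.numeric(xy$x), as.numeric(xy$y), D[,1], D[,2]), 96, 96)
lt <- log(case$phantom$sigma)
lg <- log(recg$raster); ll <- log(recl$raster)
ok <- inD & is.finite(lg) & is.finite(ll)
cat("global RMSE on D:", mreit:::rmse(lg[ok], lt[ok]), "\n")
cat("local  RMSE on D:", mreit:::rmse(ll[ok], lt[ok]), "\n")

# pipeline determinism + e2e
cfg <- list(seed = 3, stages = list(
  simulate = list(nx = 64, noise_sd = 1, contrast = 1),
  phase = list(),
  denoise = list(t1 = 0.6),
  inpaint = list(),
  mesh = list(),
  reconstruct = list()
))
m1 <- run_pipeline(cfg, "run1.rds")
m2 <- run_pipeline(cfg, "run2.rds")
h1 <- sapply(m1$stages, function(s) s$container_md5)
h2 <- sapply(m2$stages, function(s) s$container_md5)
cat("determinism:", identical(h1, h2), "\n")
cont <- read_container("run1.rds")
lt <- log(cont$sigma_true); lr <- log(cont$sigma_recon)
ok <- cont$domain_mask & is.finite(lr) & is.finite(lt)
cat("e2e noisy pearson:", cor(lr[ok], lt[ok]), "\n")
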