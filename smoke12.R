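library(mreit)
g <- slice_grid(96, 96, dx = 1.8e-3)
el <- electrode_config()
ell <- data.frame(cx=c(0,0.0), cy=c(0,0.0), a=c(0.78,0.2), b=c(0.92,0.2), angle=c(0,0), value=c(1,1.25))
case <- simulate_mreit(g, ellipses = ell, electrodes = el)
dm <- case$phantom$domain_mask
bzv <- case$bz_true
ctr <- mreit:::grid_center(g); half <- c((g$nx-1)*g$dx/2,(g$ny-1)*g$dy/2)
xy <- mreit:::grid_xy(g)
# D: central box; corruption: annulus surrounding D (like a defected torso around a brain)
rr <- sqrt(((xy$x-ctr[1])/half[1])^2 + ((xy$y-ctr[2])/half[2])^2)
annulus <- dm & rr > 0.45 & rr < 0.7
set.seed(7)
for (j in 1:2) {
  sl <- bzv$bz[,,1,j]
  sl[annulus] <- sl[annulus] + rnorm(sum(annulus), sd = 0.5*diff(range(sl[dm])))
  bzv$bz[,,1,j] <- sl
}
ph0 <- case$phantom; ph0$sigma <- matrix(1, 96, 96)
pots0 <- lapply(1:2, function(j) solve_forward_2d(ph0, el, j, mesh = case$mesh))
Js0 <- lapply(pots0, function(p) current_density(ph0, p, el))
af <- build_a_matrix(Js0[[1]], Js0[[2]])
l1 <- laplacian_bz(bzv, 1, 1); l2 <- laplacian_bz(bzv, 1, 2)
recg <- harmonic_bz_reconstruct(case$mesh, af, l1, l2)
s <- 0.4
D <- rbind(c(ctr[1]-s*half[1], ctr[2]-s*half[2]), c(ctr[1]+s*half[1], ctr[2]-s*half[2]),
           c(ctr[1]+s*half[1], ctr[2]+s*half[2]), c(ctr[1]-s*half[1], ctr[2]+s*half[2]))
Dp <- mreit:::new_domain_polygon(D)
recl <- local_harmonic_bz(Dp, af, l1, l2, g)
inD <- matrix(pracma::inpolygon(as.numeric(xy$x), as.numeric(xy$y), D[,1], D[,2]), 96, 96)
lt <- log(case$phantom$sigma)
lg <- log(recg$raster); ll <- log(recl$raster)
ok <- inD & is.finite(lg) & is.finite(ll)
cat("global RMSE on D:", mreit:::rmse(lg[ok], lt[ok]), "\n")
cat("local  RMSE on D:", mreit:::rmse(ll[ok], lt[ok]), "\n")

# e2e at 128, 1% noise, t1 = 1
cfg <- list(seed = 3, stages = list(
  simulate = list(nx = 128, noise_sd = 1),
  phase = list(), denoise = list(t1 = 1), inpaint = list(), mesh = list(), reconstruct = list()))
t0 <- Sys.time()
m <- run_pipeline(cfg, "run128.rds")
cat("pipeline t:", format(Sys.time()-t0), "\n")
cont <- read_container("run128.rds")
ltr <- log(cont$sigma_true); lr <- log(cont$sigma_recon)
ok <- cont$domain_mask & is.finite(lr) & is.finite(ltr)
cat("e2e 128 pearson:", cor(lr[ok], ltr[ok]), "\n")
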