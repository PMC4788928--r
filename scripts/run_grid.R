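#!/usr/bin/env Rscript

# Regenerates any cell block of the reference simulation grids on demand.
# The full grids take hours at M = 10000, G = 5000; choose the block, the
# replication counts and the methods from the command line.
#
#   Rscript scripts/run_grid.R --block normal_522 --reps 10000 --boot 5000 \
#           --methods t1,t2,tg,ws,wa,b1,b2,b3,b4 --seed 1 --out grid.csv
#
# Blocks:
#   normal_522 — bivariate normal, (n, n1, n2) = (5, 2, 2),
#                sigma1 in {1, sqrt(8)}, sigma2 = 4,
#                rho in {-0.9, -0.5, -0.1, 0, 0.1, 0.5, 0.9},
#                (mu1, mu2) in {(0, 0.25), (1, 1), (2, 1.5)}
#   t5_555     — bivariate t(5), same parameter grid, (5, 5, 5)
#   equal_552  — sigma1 = sigma2 = 2, (5, 5, 2), both families,
#                methods t3, t4, t5, ws, wa, b1..b4

suppressPackageStartupMessages(library(incompair))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
block <- get_arg("--block", "normal_522")
reps <- as.integer(get_arg("--reps", "10000"))
boot <- as.integer(get_arg("--boot", "5000"))
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", sprintf("grid_%s.csv", block))
methods <- strsplit(get_arg("--methods", ""), ",")[[1L]]

mus <- list(c(0, 0.25), c(1, 1), c(2, 1.5))
rhos <- c(-0.9, -0.5, -0.1, 0, 0.1, 0.5, 0.9)

make_cells <- function(family, n, n1, n2, sigmas1, sigma2) {
  cells <- list()
  for (rho in rhos) for (s1 in sigmas1) for (mu in mus) {
    id <- sprintf("%s_rho%+.1f_s1%.2f_d%+.2f", family, rho, s1,
                  mu[1] - mu[2])
    cells[[id]] <- sim_scenario(family, mu1 = mu[1], mu2 = mu[2],
                                sigma1 = s1, sigma2 = sigma2, rho = rho,
                                n = n, n1 = n1, n2 = n2,
                                M = reps, G = boot)
  }
  cells
}

cfg <- switch(block,
  normal_522 = list(
    cells = make_cells("normal", 5, 2, 2, c(1, sqrt(8)), 4),
    methods = c("t1", "t2", "tg", "ws", "wa", "b1", "b2", "b3", "b4")),
  t5_555 = list(
    cells = make_cells("t5", 5, 5, 5, c(1, sqrt(8)), 4),
    methods = c("t1", "t2", "tg", "ws", "wa", "b1", "b2", "b3", "b4")),
  equal_552 = list(
    cells = c(make_cells("normal", 5, 5, 2, 2, 2),
              make_cells("t5", 5, 5, 2, 2, 2)),
    methods = c("t3", "t4", "t5", "ws", "wa", "b1", "b2", "b3", "b4")),
  stop("unknown block: ", block))

if (length(methods) == 0L || identical(methods, "")) methods <- cfg$methods

message(sprintf("block %s: %d cells x %d methods, M = %d, G = %d",
                block, length(cfg$cells), length(methods), reps, boot))
t0 <- Sys.time()
grid <- run_grid(cfg$cells, methods, seed = seed)
write.csv(grid, out, row.names = FALSE)
message(sprintf("wrote %s (%.1f min)", out,
                as.numeric(difftime(Sys.time(), t0, units = "mins"))))
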