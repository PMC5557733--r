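# Shared fixtures (built once per test run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tpl_small <- function() fixture("tpl_small", function() make_template(800L))
tpl_mid <- function() fixture("tpl_mid", function() make_template(2000L))
tpl_full <- function() fixture("tpl_full", function() make_template())

# random rigid motion (rotation + translation), deterministic in seed
rigid_motion <- function(seed) {
  r <- withr::with_seed(seed, stats::rnorm(6))
  rot1 <- matrix(c(1, 0, 0, 0, cos(r[1]), -sin(r[1]),
                   0, sin(r[1]), cos(r[1])), 3, 3, byrow = TRUE)
  rot2 <- matrix(c(cos(r[2]), -sin(r[2]), 0, sin(r[2]), cos(r[2]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
  list(R = rot1 %*% rot2 %*% t(rot1), t = r[4:6] * 3)
}

move_points <- function(p, mo) {
  p %*% t(mo$R) + rep(mo$t, each = nrow(p))
}

move_specimen <- function(s, mo) {
  s$mesh$vertices <- move_points(s$mesh$vertices, mo)
  p <- move_points(cbind(s$landmarks$x, s$landmarks$y, s$landmarks$z), mo)
  s$landmarks$x <- p[, 1]; s$landmarks$y <- p[, 2]; s$landmarks$z <- p[, 3]
  s
}

# independent synchronous GrowCut oracle (array-shift implementation)
growcut_oracle <- function(intens, labels, max_iters = 100) {
  rng <- range(intens)
  C <- if (rng[2] > rng[1]) (intens - rng[1]) / (rng[2] - rng[1])
       else array(0, dim(intens))
  d <- dim(C)
  lab <- labels
  str <- array(as.numeric(labels != 0L), d)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  shift3 <- function(a, o, fill) {
    out <- array(fill, d)
    sx <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    sy <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    sz <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    out[sx, sy, sz] <- a[sx - o[1], sy - o[2], sz - o[3]]
    out
  }
  for (it in seq_len(max_iters)) {
    best_s <- str
    best_l <- lab
    for (k in seq_len(nrow(offs))) {
      o <- as.integer(offs[k, ])
      lq <- shift3(lab, o, 0L)
      sq <- shift3(str, o, 0)
      cq <- shift3(C, o, Inf)
      g <- (1 - abs(C - cq)) * sq
      win <- lq != 0L & g > best_s
      best_s[win] <- g[win]
      best_l[win] <- lq[win]
    }
    changed <- any(best_l != lab)
    lab <- best_l
    str <- best_s
    if (!changed) break
  }
  list(label = lab, strength = str, iterations = it, converged = !changed)
}

# brute-force binary morphology oracle with a ball structuring element
morph_oracle <- function(mask, r, dilate) {
  d <- dim(mask)
  out <- array(NA, d)
  offs <- expand.grid(dx = -floor(r):floor(r), dy = -floor(r):floor(r),
                      dz = -floor(r):floor(r))
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= r^2 + 1e-12, ]
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    xs <- x + offs$dx; ys <- y + offs$dy; zs <- z + offs$dz
    ok <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2] & zs >= 1 & zs <= d[3]
    vals <- rep(FALSE, nrow(offs))
    vals[ok] <- mask[cbind(xs[ok], ys[ok], zs[ok])]
    out[x, y, z] <- if (dilate) any(vals) else all(vals)
  }
  out
}

# unit sphere mesh (closed) for phantom tests
sphere_mesh <- function(n = 4000, radius = 1) {
  m <- mandmap:::.ring_tessellation(n, c(x = radius, y = radius, z = radius))
  m
}
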