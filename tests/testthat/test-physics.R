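# Flight-physics layer: acceleration time, height-dependent TOF, the
# shift law and the quadratic mass calibration.

test_that("acceleration time matches the conventional K+ estimate and scales as sqrt(m)", {
  geom <- instrumentGeometry()
  # 2 kV over 1.5 mm with the atomic weight of potassium: ~30.2 ns
  expect_equal(signif(accelerationTime(ionMasses[["K_atomic"]], geom) * 1e9, 3),
               30.2)
  # monoisotopic 39K gives a slightly smaller value
  expect_lt(accelerationTime(ionMasses[["K"]], geom),
            accelerationTime(ionMasses[["K_atomic"]], geom))
  # sqrt-mass scaling: quadrupled mass doubles the time
  m <- 50
  expect_equal(accelerationTime(4 * m, geom), 2 * accelerationTime(m, geom))
  # height scaling sqrt((h_ex - dh)/h_ex), decreasing in dh
  dh <- c(0, 5e-6, 5e-5, 2e-4, 1e-3)
  tt <- accelerationTime(m, geom, dh)
  expect_equal(tt / tt[1], sqrt((geom@h_ex - dh) / geom@h_ex))
  expect_true(all(diff(tt) < 0))
  expect_error(accelerationTime(m, geom, geom@h_ex), "dh")
  expect_error(accelerationTime(m, geom, -1e-6), "dh")
  expect_error(accelerationTime(-1, geom), "mass")
})

test_that("total TOF anchors on the calibration ion and obeys the shift law", {
  geom <- instrumentGeometry()
  # substrate-level K+ flies the calibrated 20.545 us
  expect_equal(totalTof(ionMasses[["K"]], 0, geom), 20.545e-6)
  # Cs+ substrate TOF from sqrt(m) scaling: 20.545us * sqrt(132.9055/38.9637)
  expect_equal(totalTof(ionMasses[["Cs"]], 0, geom), 3.7944387e-5,
               tolerance = 1e-7)
  # frozen hand evaluations of the shift law (t_ac0 * (1 - sqrt(1 - dh/h)))
  expect_equal(tofShift(ionMasses[["K"]], 200e-6, geom), 2.0814e-9,
               tolerance = 1e-4)
  expect_equal(tofShift(ionMasses[["Cs"]], 200e-6, geom), 3.8440e-9,
               tolerance = 1e-4)
  # elevated emission always arrives earlier, strictly increasing shift
  dh <- seq(0, 4e-4, by = 1e-5)
  sh <- tofShift(ionMasses[["K"]], dh, geom)
  expect_equal(sh[1], 0)
  expect_true(all(diff(sh) > 0))
  expect_equal(totalTof(ionMasses[["K"]], dh, geom),
               totalTof(ionMasses[["K"]], 0, geom) - sh)
})

test_that("closed-form flight times agree with numerical integration of the equation of motion", {
  library(deSolve)
  geom <- instrumentGeometry()
  uamu <- 1.66053906660e-27
  e <- 1.602176634e-19
  set.seed(42)
  for (i in 1:20) {
    m <- runif(1, 10, 300)
    dh <- runif(1, 0, 0.9 * geom@h_ex)
    a <- geom@U_ex * e / (m * uamu * geom@h_ex)   # uniform field U/h
    yini <- c(x = dh, v = 0)
    root <- function(t, y, p) y["x"] - geom@h_ex
    sol <- lsodar(yini, times = c(0, 1e-6),
                  func = function(t, y, p) list(c(y["v"], a)),
                  rootfunc = root, rtol = 1e-12, atol = 1e-15)
    tArr <- attr(sol, "troot")
    expect_equal(tArr, accelerationTime(m, geom, dh), tolerance = 1e-9)
  }
})

test_that("quadratic mass calibration inverts exactly and hits its anchors", {
  geom <- instrumentGeometry()
  expect_equal(massFromTof(geom@T_cal, geom), geom@m_cal)
  expect_equal(massFromTof(2 * geom@T_cal, geom), 4 * geom@m_cal)
  # inverse of the Cs substrate TOF example
  expect_equal(massFromTof(37.945e-6, geom), 132.91, tolerance = 1e-4)
  # round trips at floating precision, with and without offset
  masses <- c(0.5, 22.9898, 38.9637, 132.9055, 265.8109)
  expect_equal(massFromTof(tofFromMass(masses, geom), geom), masses)
  expect_equal(massFromTof(tofFromMass(masses, geom, t0 = 3e-8), geom,
                           t0 = 3e-8), masses)
  expect_error(massFromTof(0, geom), "t0")
  expect_error(tofFromMass(-1, geom), "mass")
})

test_that("height reconstruction is the exact inverse of the shift law", {
  geom <- instrumentGeometry()
  m <- ionMasses[["Cs"]]
  for (dh in c(5e-6, 5e-5, 2e-4, 4e-4, 0.9 * geom@h_ex)) {
    expect_equal(heightFromShift(tofShift(m, dh, geom), m, geom), dh,
                 tolerance = 1e-12 / dh)
  }
  expect_equal(heightFromShift(0, m, geom), 0)
  expect_error(heightFromShift(accelerationTime(m, geom), m, geom), "t_ac")
})

test_that("the relative topographic shift is mass-independent", {
  geom <- instrumentGeometry()
  set.seed(7)
  for (i in 1:25) {
    m1 <- runif(1, 5, 300); m2 <- runif(1, 5, 300)
    dh <- runif(1, 0, 0.95 * geom@h_ex)
    r1 <- totalTof(m1, dh, geom) / totalTof(m1, 0, geom)
    r2 <- totalTof(m2, dh, geom) / totalTof(m2, 0, geom)
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("the detectable height floor at one-bin timing accuracy is about 5 um", {
  expect_equal(signif(detectableHeightFloor() * 1e6, 1), 5)
})

test_that("instrument geometry validates its physical invariants", {
  geom <- instrumentGeometry()
  expect_equal(nBins(geom), 2000000L)
  expect_error(instrumentGeometry(U_ex = -5), "positive")
  expect_error(instrumentGeometry(tof_bin = 2e-4), "t_window")
  expect_error(instrumentGeometry(T_cal = 2e-4), "window")
  expect_silent(validObject(geom))
  # JSON round trip preserves every field
  g2 <- geometryFromJSON(geometryToJSON(geom))
  for (f in c("U_ex", "h_ex", "T_cal", "m_cal", "tof_bin", "t_window"))
    expect_equal(slot(g2, f), slot(geom, f))
})
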