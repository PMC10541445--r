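# Shared desk-scale fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

deskGeometry <- function() {
  if (is.null(.fx$geom))
    .fx$geom <- detectorGeometry(nFast = 41L, nSlow = 41L, pixelSize = 2400)
  .fx$geom
}

deskPixmap <- function() {
  if (is.null(.fx$pm)) .fx$pm <- buildPixelMap(deskGeometry())
  .fx$pm
}

deskGrid <- function() {
  pm <- deskPixmap()
  list(edge = 33L, dq = max(pm@qmag) / 15)
}

deskParticle <- function() {
  if (is.null(.fx$particle)) .fx$particle <- makeToyParticle(40, 25, seed = 1)
  .fx$particle
}

deskTruth <- function() {
  if (is.null(.fx$truth)) {
    g <- deskGrid()
    .fx$truth <- idealIntensityVolume(deskParticle(), g$edge, g$dq)
  }
  .fx$truth
}

deskRotations <- function(level = 4L) sampleRotations(level)

# random unit quaternion stream independent of the global RNG
fixedQuats <- function(n, seed = 7) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  q <- randomRotations(n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  q
}
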