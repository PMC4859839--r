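# Gaussian basis-set library and shell construction.
#
# Exponents and contraction coefficients are the standard published STO-3G and
# 6-31G parameters.  Only s and p shells are shipped, which covers every
# element appearing in the package's model systems (H, He, Li, C, N, O).

.ELEMENT_Z <- c(H = 1, He = 2, Li = 3, C = 6, N = 7, O = 8)

.STO3G_1S_COEF <- c(0.1543289673, 0.5353281423, 0.4446345422)
.STO3G_2S_COEF <- c(-0.09996722919, 0.3995128261, 0.7001154689)
.STO3G_2P_COEF <- c(0.1559162750, 0.6076837186, 0.3919573931)

.BASIS_LIBRARY <- list(
  "sto-3g" = list(
    H = list(list(l = 0L,
                  exp = c(3.425250914, 0.6239137298, 0.1688554040),
                  coef = .STO3G_1S_COEF)),
    He = list(list(l = 0L,
                   exp = c(6.362421394, 1.158922999, 0.3136497915),
                   coef = .STO3G_1S_COEF)),
    Li = list(
      list(l = 0L, exp = c(16.11957475, 2.936200663, 0.794650487),
           coef = .STO3G_1S_COEF),
      list(l = 0L, exp = c(0.6362897469, 0.1478600533, 0.0480886784),
           coef = .STO3G_2S_COEF),
      list(l = 1L, exp = c(0.6362897469, 0.1478600533, 0.0480886784),
           coef = .STO3G_2P_COEF)),
    C = list(
      list(l = 0L, exp = c(71.61683735, 13.04509632, 3.530512160),
           coef = .STO3G_1S_COEF),
      list(l = 0L, exp = c(2.941249355, 0.6834830964, 0.2222899159),
           coef = .STO3G_2S_COEF),
      list(l = 1L, exp = c(2.941249355, 0.6834830964, 0.2222899159),
           coef = .STO3G_2P_COEF)),
    N = list(
      list(l = 0L, exp = c(99.10616896, 18.05231239, 4.885660238),
           coef = .STO3G_1S_COEF),
      list(l = 0L, exp = c(3.780455879, 0.8784966449, 0.2857143744),
           coef = .STO3G_2S_COEF),
      list(l = 1L, exp = c(3.780455879, 0.8784966449, 0.2857143744),
           coef = .STO3G_2P_COEF)),
    O = list(
      list(l = 0L, exp = c(130.7093214, 23.80886605, 6.443608313),
           coef = .STO3G_1S_COEF),
      list(l = 0L, exp = c(5.033151319, 1.169596125, 0.3803889600),
           coef = .STO3G_2S_COEF),
      list(l = 1L, exp = c(5.033151319, 1.169596125, 0.3803889600),
           coef = .STO3G_2P_COEF))
  ),
  "6-31g" = list(
    H = list(
      list(l = 0L, exp = c(18.73113696, 2.825394365, 0.6401216923),
           coef = c(0.03349460434, 0.2347269535, 0.8137573261)),
      list(l = 0L, exp = 0.1612777588, coef = 1.0)),
    C = list(
      list(l = 0L,
           exp = c(3047.524880, 457.3695180, 103.9486850, 29.21015530,
                   9.286662960, 3.163926960),
           coef = c(0.001834737132, 0.01403732281, 0.06884262226,
                    0.2321844432, 0.4679413484, 0.3623119853)),
      list(l = 0L, exp = c(7.868272350, 1.881288540, 0.5442492580),
           coef = c(-0.1193324198, -0.1608541517, 1.143456438)),
      list(l = 1L, exp = c(7.868272350, 1.881288540, 0.5442492580),
           coef = c(0.06899906659, 0.3164239610, 0.7443082909)),
      list(l = 0L, exp = 0.1687144782, coef = 1.0),
      list(l = 1L, exp = 0.1687144782, coef = 1.0)),
    N = list(
      list(l = 0L,
           exp = c(4173.511460, 627.4579110, 142.9020930, 40.23432930,
                   12.82021290, 4.390437010),
           coef = c(0.001834772160, 0.01399462700, 0.06858655181,
                    0.2322408730, 0.4690699481, 0.3604551991)),
      list(l = 0L, exp = c(11.62636186, 2.716279807, 0.7722183966),
           coef = c(-0.1149611817, -0.1691174786, 1.145851947)),
      list(l = 1L, exp = c(11.62636186, 2.716279807, 0.7722183966),
           coef = c(0.06757974388, 0.3239072959, 0.7408951398)),
      list(l = 0L, exp = 0.2120314975, coef = 1.0),
      list(l = 1L, exp = 0.2120314975, coef = 1.0)),
    O = list(
      list(l = 0L,
           exp = c(5484.671660, 825.2349460, 188.0469580, 52.96450000,
                   16.89757040, 5.799635340),
           coef = c(0.001831074430, 0.01395017220, 0.06844507810,
                    0.2327143360, 0.4701928980, 0.3585208530)),
      list(l = 0L, exp = c(15.53961625, 3.599933586, 1.013761750),
           coef = c(-0.1107775495, -0.1480262627, 1.130767015)),
      list(l = 1L, exp = c(15.53961625, 3.599933586, 1.013761750),
           coef = c(0.07087426823, 0.3397528391, 0.7271585773)),
      list(l = 0L, exp = 0.2700058226, coef = 1.0),
      list(l = 1L, exp = 0.2700058226, coef = 1.0))
  )
)

#' Available basis sets
#' @return Character vector of basis-set names accepted by the EDA functions.
#' @export
available_bases <- function() names(.BASIS_LIBRARY)

element_number <- function(symbol) {
  z <- .ELEMENT_Z[symbol]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "),
         "; supported: ", paste(names(.ELEMENT_Z), collapse = ", "))
  }
  unname(z)
}

.dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

# Primitive normalization constant for the (l,0,0) Cartesian component.
.prim_norm <- function(a, l) {
  (2 * a / pi)^0.75 * sqrt((4 * a)^l / .dfact(2 * l - 1))
}

# Normalize one contracted shell: fold primitive norms into the coefficients,
# then rescale so the contracted (l,0,0) component has unit self-overlap.
.normalize_shell <- function(exps, coefs, l) {
  c1 <- coefs * vapply(exps, .prim_norm, numeric(1), l = l)
  p <- outer(exps, exps, "+")
  s_prim <- (pi / p)^1.5 * .dfact(2 * l - 1) / (2 * p)^l
  self <- as.numeric(t(c1) %*% s_prim %*% c1)
  c1 / sqrt(self)
}

# Build the engine shell list for a set of atoms.  `ghost` atoms contribute
# basis functions but no nuclear charge (handled by the caller); coordinates
# in angstrom.
build_shells <- function(elements, xyz, basis = "sto-3g") {
  basis <- tolower(basis)
  lib <- .BASIS_LIBRARY[[basis]]
  if (is.null(lib)) {
    stop("basis '", basis, "' not available; choose one of: ",
         paste(available_bases(), collapse = ", "))
  }
  shells <- list()
  for (i in seq_along(elements)) {
    el <- elements[i]
    bs <- lib[[el]]
    if (is.null(bs)) {
      stop("basis '", basis, "' has no parameters for element ", el)
    }
    for (sh in bs) {
      shells[[length(shells) + 1L]] <- list(
        l = sh$l,
        center = as.numeric(xyz[i, ]) * .BOHR_PER_ANGSTROM,
        exponents = sh$exp,
        coefficients = .normalize_shell(sh$exp, sh$coef, sh$l),
        atom = i)
    }
  }
  shells
}

n_basis_functions <- function(shells) {
  sum(vapply(shells, function(s) (s$l + 1L) * (s$l + 2L) / 2L, numeric(1)))
}
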