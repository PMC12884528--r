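---
title: "Atomistic fluctuating-charge plasmonics and surface-enhanced vibrational spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atomistic fluctuating-charge plasmonics and surface-enhanced vibrational spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmovib)
```

## The physical model

`plasmovib` computes the frequency-domain optical response of metal and
graphene nanostructures with *fully atomistic* classical electrodynamics, and
couples that response to a point-multipole vibrational model of an adsorbed
molecule to predict surface-enhanced infrared absorption (SEIRA) and
surface-enhanced Raman scattering (SERS) intensities.

### Fluctuating charges (wFQ)

Every substrate atom $p$ carries a complex charge $q_p(\omega)$.  Charge flows
between nearest neighbours by Drude conduction, damped by a Fermi-like
function that mimics quantum tunneling through the interatomic gap.  The
charges solve

$$\left[\bar K\, T^{qq} - z_q(\omega)\, I_N\right] q(\omega)
  = -\bar K\, V^{\mathrm{ext}}(\omega),$$

where $T^{qq}$ is the (regularized) charge–charge Coulomb kernel,
$V^{\mathrm{ext}}$ the external potential at the atoms, and $\bar K$ the
charge-conserving conduction matrix built from

$$K_{ij} = \bigl[1 - f(r_{ij})\bigr]\,\frac{\sqrt{A_i A_j}}{r_{ij}},\qquad
  \bar K_{ij} = K_{ij} - \delta_{ij}\sum_k K_{ik},\qquad
  f(r) = \frac{1}{1 + e^{-d\,(r/(s\,r^0) - 1)}}.$$

$K$ is restricted to the neighbour graph (cutoff $1.2\,r^0$ by default),
reflecting that conduction is a nearest-neighbour process.  Because the rows
and columns of $\bar K$ sum to zero, $\sum_p q_p = 0$ holds *structurally*
for every source and frequency — the package tests assert this on every
solve.  The frequency enters only through the complex scalar

$$z_q(\omega) = -\frac{\omega\,(\omega\tau + i)}{2 n \tau},$$

with $\tau$ the Drude relaxation time and $n$ the effective electron density.

Two conventions deserve a note, since both appear in the literature with
different prefactors.  A first-principles discretization of Drude conduction
on the neighbour graph ($\dot q_i = \sum_j g_{ij}(V_j - V_i)$ with bond
conductance $g = \sigma A / r$ and $\sigma = n\tau/(1 - i\omega\tau)$) yields
$z_q = -\omega(\omega\tau + i)/(n\tau)$, i.e. without the factor 2.  We adopt
the factor-2 form above and absorb the difference into the default effective
areas: multiplying $z_q$ by $\tfrac12$ and $A_i$ by $\tfrac12$ leaves the
solution identical.  `z_q()` is deliberately a one-line function so the
convention can be audited (and changed) in one place.

The geometric mean $\sqrt{A_i A_j}$ in $K_{ij}$ keeps the matrix symmetric
for heterogeneous atoms and reduces to the plain $A_i$ form for a uniform
material; symmetry of the full system matrix is what makes the response
reciprocal (see the reciprocity test below).

### Fluctuating charges and dipoles (wFQFmu)

Noble metals are not Drude-only: the polarizable d-shell screens the
conduction electrons.  Each atom therefore additionally carries a complex
point dipole $\mu_p(\omega)$ governed by a frequency-dependent interband
atomic polarizability $\alpha_{\mathrm{IB}}(\omega)$, through
$z_\mu(\omega) = -1/\alpha_{\mathrm{IB}}(\omega)$.  Charges and dipoles are
coupled by the block system

$$\left[
 \begin{pmatrix}\bar K & 0\\ 0 & I_{3N}\end{pmatrix}
 \begin{pmatrix}T^{qq} & T^{q\mu}\\ T^{\mu q} & T^{\mu\mu}\end{pmatrix}
 - \begin{pmatrix}z_q I_N & 0\\ 0 & z_\mu I_{3N}\end{pmatrix}
\right]
\begin{pmatrix}q\\ \mu\end{pmatrix}
=
\begin{pmatrix}\bar K & 0\\ 0 & I_{3N}\end{pmatrix}
\begin{pmatrix}-V^{\mathrm{ext}}\\ E^{\mathrm{ext}}\end{pmatrix}.$$

An isolated atom decouples to $\mu = \alpha_{\mathrm{IB}}E$, which the test
suite checks literally.

### Graphene

For graphene the same wFQ machinery applies with an effective 3D density that
is *linear in the Fermi energy*,

$$n = \frac{E_F}{\pi\, a_0\, \hbar\, v_F},$$

consistent with $E_F = \hbar v_F \sqrt{\pi n_{2D}}$ for Dirac carriers.  This
is what makes graphene's plasmon electrically tunable: the package's property
tests assert that the disk resonance blueshifts strictly with $E_F$ and
redshifts strictly with disk diameter, following the expected
$\sqrt{E_F/D}$ law.

## Electrostatic kernels and regularization

All interaction kernels derive from one scalar function, the erf-screened
Coulomb potential $T(r) = \mathrm{erf}(r/W)/r$ of two Gaussian charge
distributions with combined width $W = \sqrt{w_i^2 + w_j^2}$:
$T^{q\mu} = -\nabla T$ applied on the potential row, $T^{\mu q}$ its
transpose on the field row, and $T^{\mu\mu} = -\nabla\nabla T$.  Gaussian
smearing is the established regularization in discrete-interaction models: it
keeps every kernel finite at contact (self-interaction
$2/(\sqrt{\pi} W)$) while reducing to the bare $1/r$, dipole, and
dipole–dipole tensors in the far field.  The width is a material parameter
(`reg_width`, default half the nearest-neighbour distance); results at the
plasmon resonance are insensitive to moderate changes because the resonance
is a collective mode dominated by far-field Coulomb interactions.

Crucially, the *same* kernels evaluate the molecular potential/field on the
substrate, the scattered field at external points, and the
substrate–substrate blocks.  This consistency is not cosmetic: it is what
makes the two SEIRA routes — solving with molecular sources and reducing to
the induced dipole, versus dressing the transition dipole with the transposed
local-field tensor $\Lambda^T$ — agree to machine precision (the
electromagnetic reciprocity test).

## Default material parameters

The exact parameter sets used in published work live in dedicated
parametrization papers and are not reproduced here; the package ships
physically motivated defaults, stated openly so they can be replaced via
`material_params()` or a YAML config when quantitative resonance positions
matter:

* **Gold** — $n = 3/(4\pi r_s^3)$ with $r_s = 3.01$ Bohr
  ($n \approx 8.75\times10^{-3}$ au, bulk plasmon $\approx 9$ eV);
  $\tau = 1/(0.071\ \mathrm{eV})\approx 380$ au from the bulk Drude damping;
  $A_i = 3\,\Omega_{\mathrm{atom}}/(Z r^0) = r_0^2/(4\sqrt2)$ from
  bulk-conduction matching on the fcc lattice ($Z = 12$,
  $\Omega_{\mathrm{atom}} = r_0^3/\sqrt2$), including the factor-$\tfrac12$
  convention above.  With these defaults a 309-atom Drude icosahedron
  resonates within 10% of the classical sphere limit
  $\omega_p/\sqrt3$ — an internal consistency check requiring no empirical
  input.
* **Gold interband** — a three-Lorentzian
  $\alpha_{\mathrm{IB}}(\omega) = \sum_k f_k/(\omega_k^2 - \omega^2 -
  i\gamma_k\omega)$ with static value $\approx 19$ au$^3$ and oscillators at
  2.7/3.05/4.0 eV, reproducing the qualitative d-band onset.  A tabulated
  $\alpha_{\mathrm{IB}}$ (e.g. from a published fit) can be supplied through
  `interband_table()` for quantitative plasmon positions.
* **Graphene** — $v_F = c/300 \approx 0.457$ au; Drude damping 0.010 eV;
  $A_i = 2 S_{\mathrm{atom}} v_F /(3 c_{\mathrm{CC}})$ from two-dimensional
  conduction matching against the Dirac sheet Drude weight $E_F/\pi$ (note
  $E_F$ cancels, so the area is a material constant and the resonance scales
  as $\sqrt{E_F}$, as it must).
* **Tunneling** — $d = 35$, $s = 1.2$: conduction is $\gtrsim 99\%$ of its
  nominal value at the equilibrium bond length and halves at $1.2\,r^0$.
  These shape junction and gap physics, not the single-particle resonances
  studied here.

## From substrate response to spectra

The polarizability tensor collects the induced dipole
$\sum_p (q_p r_p + \mu_p)$ for unit probes along $x,y,z$; the
orientation-averaged absorption cross-section is the quasi-static
$\sigma(\omega) = (4\pi\omega/c)\,\mathrm{Im}\,\mathrm{tr}\,\alpha/3$, and
the plasmon resonance frequency (PRF) is the refined position of its global
maximum.  We locate the PRF on $\sigma(\omega)$ (rather than on
$\mathrm{Im}\,\alpha$): for the narrow resonances involved the two peak
within grid resolution of each other, and $\sigma$ is the observable.  A
3-point parabola refines the maximum below the grid spacing (default grids:
0.005 eV for metals, 5 cm$^{-1}$ for the infrared); ties break toward lower
frequency, a flat spectrum warns and returns its lowest maximizer, and a
boundary maximum warns that the grid does not bracket the resonance.

## The molecular surrogate

The molecule is represented by point multipoles: partial charges (plus
optional fixed dipoles), per-atom atomic polar tensors (APTs)
$\partial d/\partial R$, mass-weighted normal modes, and per-mode
polarizability derivatives $\partial\alpha/\partial Q$.  The gas-phase dipole
is linearized through the APTs,
$d(R) = \sum_a q_a R_a + \sum_a (\mathrm{APT}_a - q_a I)(R_a - R_a^0)$, so a
displaced geometry carries its charge at the displaced position plus an
induced point dipole — keeping the source multipoles consistent with the
dipole function, and reducing exactly to the point-charge picture when
$\mathrm{APT}_a = q_a I$.  The multipolar expansion of the molecular density
is truncated at these point charges and dipoles; that truncation is the
documented meaning of "molecular density" everywhere in the package.

`make_fixture()` generates a seeded synthetic surrogate: a planar purine-like
fused-ring skeleton with outward substituents, bounded random charges
($|q|\le0.5$, exactly neutral), APTs scattered around their point-charge
values, $3n-6$ orthonormal mass-weighted modes with frequencies drawn in
400–1800 cm$^{-1}$, and random symmetric polarizability derivatives.  It
emulates the *structure* of quantum-chemical vibrational data — realistic
geometry, charge magnitudes, mode count and frequency window — but not real
normal-mode physics: its mode vectors are random orthonormal directions, its
frequencies carry no force-field information, and intensity patterns are
statistical.  Tests passing on the surrogate therefore validate the coupling
algebra, conservation laws, scaling laws and enhancement bookkeeping; they do
not certify agreement with any measured spectrum of a real molecule.

## SEIRA and SERS

For SEIRA, each mode's intensity derives from the *external* dipole
$d + \tilde d$: the gas-phase dipole plus the dipole induced on the substrate
by the oscillating molecular density,

$$-\tilde d\cdot E^{\mathrm{ext}} =
  \sum_p \left[ q_p V^{\mathrm{ext}}(r_p) - \mu_p\cdot E^{\mathrm{ext}}(r_p)\right],$$

with the substrate solved at the normal-mode frequency.  The derivative
$\partial(d + \tilde d)/\partial Q_i$ is taken by the 3-point central scheme
with a displacement of 0.001 Bohr cartesian norm along the mode vector
(0.0005 Bohr available as a stability check; the two agree to a relative
$10^{-4}$ in the tests).  Enhancement factors follow per mode:
$\mathrm{EF}_i = I_i/I_i^{\mathrm{vac}}$, the intensity-weighted average
$\mathrm{AEF} = \sum_i I_i / \sum_i I_i^{\mathrm{vac}}$, the maximum
$\mathrm{MEF}$, and the mode attaining it ($i$-MEF, ties toward the lowest
frequency).  Modes with vanishing vacuum intensity are excluded from the
per-mode factors but kept in the AEF sums.

SERS is computed as a *declared classical surrogate* of the full
quantum-mechanical coupled-perturbed treatment: each mode's polarizability
derivative is dressed with the local field tensor at the molecular centroid,
$a^{\mathrm{eff}}_i = \Lambda^T(\omega_{\mathrm{inc}})\,
(\partial\alpha/\partial Q_i)\,\Lambda(\omega_{\mathrm{inc}})$, with a
0.10 eV phenomenological lifetime added to the substrate response (the
frequency is continued to $\omega + i\gamma/2$), and intensities follow from
the standard rotational invariants $45|a|^2 + 7\gamma^2$.  The dressing is
evaluated at the incident frequency only — no Stokes shift of the local
field — matching the single-incident-frequency protocol; the incident
frequency is normally placed at the substrate PRF.  This surrogate preserves
the physics the enhancement analysis relies on: the quartic local-field
scaling (versus quadratic for SEIRA; in the scalar-isotropic limit
$\mathrm{EF}_{\mathrm{SERS}} = \mathrm{EF}_{\mathrm{SEIRA}}^2$ exactly),
reciprocity, and mode selectivity at resonance.  It omits chemical
(charge-transfer) enhancement, image-field self-consistency with a quantum
density, and molecular resonance-Raman effects.  Ground-state
molecule–substrate coupling is likewise omitted; its effect on these signals
is marginal in the regime of interest.

## Numerical choices

* **Solvers.** Dense LU factorization below 4000 atoms (1000 for the coupled
  charge–dipole system); above that, kernels are applied matrix-free in
  chunked pairwise sums and systems are solved with a hand-rolled complex
  restarted GMRES (relative residual $10^{-8}$, 2000-iteration cap,
  warm-startable).  The dense route is the oracle for the iterative one: on
  random clusters both agree to $10^{-8}$ relative, for both response
  systems, and the block solver matches a monolithic $4N\times4N$
  factorization to machine precision.
* **Static limit.** $z_q(0) = 0$ makes the system singular — physically, the
  static problem is constrained charge equilibration, which the
  low-frequency solution approaches (verified on a 10-atom chain); an exact
  $\omega = 0$ solve raises an informative error instead of returning noise.
* **Degenerate inputs.** Coincident atoms, asymmetric neighbour graphs,
  overlapping molecules (steric clashes below 1.5 Å), all-zero vacuum
  spectra, and out-of-range interband queries raise errors naming the
  offending quantity.
* **Problem sizes.** The shipped tests and the acceptance script run on
  desk-scale systems chosen to exercise every code path while completing in
  minutes: icosahedra of 13–10,179 atoms (the builders are checked against
  the closed-form magic numbers up to 104,223), graphene disks of 4–6 nm
  (480–1080 atoms), and random clusters of 15–40 atoms for the oracle
  comparisons.  The mode-selectivity demonstration uses low Fermi energies
  (0.015–0.030 eV) on a small disk: by the $\sqrt{E_F/D}$ law this
  reproduces, at desk scale, the resonance positions that tens-of-nanometre
  disks reach at 0.1–0.4 eV — the same emulation trick the tunability of
  graphene affords experimentally.

## Known limitations

The electrodynamics is quasi-static (no retardation), appropriate for
structures well below the wavelength.  Substrate-induced changes to the
molecular normal modes are neglected (modes are taken from the isolated
molecule).  The shipped material parameters are qualitative stand-ins:
resonance positions with them are internally consistent (sphere limit,
scaling laws) but not fitted to experiment — quantitative work should supply
tabulated interband data and literature Drude parameters through the material
config.  Periodic boundary conditions, defected or doped lattices, nanoalloys
and solvent effects are out of scope.

## A worked micro-example

```{r example, eval = FALSE}
gd  <- neighbor_graph(build_graphene_disk(4), 1.1 * 1.42)
par <- graphene_material(0.022)
sp  <- absorption_spectrum(gd, par,
                           seq(cm1_to_ev(500), cm1_to_ev(2200),
                               length.out = 30), "wfq")
mol <- place(make_fixture(1, n_atoms = 8), gd,
             placement(anchor_atom = 1, distance = 3.5, mode = "face_on"))
rep <- seira_intensities(mol, gd, par, "wfq")
ev_to_cm1(sp$prf)                # disk plasmon, ~1423 cm^-1
rep$frequencies[rep$i_mef]       # most-enhanced mode, ~1425 cm^-1
```

The most-enhanced vibrational mode coincides with the disk's plasmon
resonance — the mode-selective amplification that makes tunable graphene
substrates attractive for infrared sensing.
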