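# polyfold

Monte Carlo–molecular dynamics simulation of methylation-driven chromatin
folding by Polycomb complexes.

## The problem

In *Drosophila*, Polycomb-repressed genes sit inside broad
H3K27-trimethylated chromatin domains, yet PRC1 — the complex that reads
the mark — binds stably only at discrete Polycomb Response Elements
(PREs). If the methylation mark does not recruit PRC1 to genes, what is it
for? `polyfold` implements a hybrid simulation framework built to answer
that question: chromatin is a coarse-grained bead-spring polymer (one bead
= one 10 nm nucleosome), PRC1 occupancy of PREs is redrawn
probabilistically before every dynamics round, and occupied PREs attract
methylated beads through a calibrated short-range well. Stochastic
PRE–nucleosome looping alone folds the methylated locus to roughly half
its unfolded volume, survives two-fold post-replication dilution of the
mark, and spatially clusters the PREs without any direct PRE–PRE
interaction.

The package is aimed at chromatin biophysicists and quantitative
epigenomics researchers who want a self-contained, scriptable version of
this model class — no external MD engine required.

## The model in brief

A chain of $N$ beads (default 360 ≈ 63 kb) evolves under Langevin dynamics

$$m\ddot{r}_i = -\Gamma \dot r_i - \nabla V(r_i) + W_i(t),$$

with $V$ summing FENE bonds ($K_s = 30\,k_BT$, $R_0 = 1.5\sigma$), cosine
bending ($K_\theta = 3\,k_BT$, $l_p \approx 2.7\sigma$ measured), WCA
excluded volume ($\epsilon_{ev} = 1\,k_BT$), and — only between
PRC1-occupied PREs and methylated beads — a Lennard-Jones well of depth
$\epsilon$ truncated at $r_{int} = 2.5\sigma$. Occupancy is Bernoulli per
PRE with probability $p_b^{PRE} = c_{PRC1}/(c_{PRC1} + K_D^{PRE})$.

The attraction strength is calibrated to the measured PRC1–H3K27me3
affinity ($K_D \sim 5$ µM) twice: in closed form,
$\epsilon = -\tfrac{1}{0.938}\ln(K_D/c_0) = 6.20\,k_BT$ with
$c_0 = 1/(N_A\sigma^3)$, and by a many-particle binding simulation whose
bound fraction crosses 0.5 at $\epsilon \approx 3.9\,k_BT$; the consensus
mean 5.1 $k_BT$ is the production value. Folding is read out as the locus
volume $V = \tfrac43\pi R_g^3$ relative to a no-PRE reference chain.

## Worked example

```r
library(polyfold)

# The calibration chain, in numbers
well_depth(1, 2.0)                 # -0.938  (well depth per unit epsilon)
standard_state(10)                 # 0.00166 M (one particle per bead volume)
eps_from_kd(5e-6, c0 = 1.67e-3)    # 6.20 kBT for KD = 5 uM
eps_consensus(3.94, 6.20)          # 5.07 -> production eps = 5.1 kBT
kd_for_pb(0.5, 0.2e-6) * 1e9       # 200 nM: KD_PRE for half occupancy

# Anchored-loop model of PRE clustering
for (cfg in 1:3) {
  mc <- mean_anchor_distance(loop_model_config(cfg, seed = 1))
  cat(sprintf("config %d: mean anchor distance %.3f\n", cfg, mc$mean))
}

# Fold a small locus: 60-mer, 20-bead methylated core, 2 PREs
topo <- make_fixture("chain60")$topo
ffp  <- forcefield_params()        # eps = 5.1 kBT
dp   <- dynamics_params()
st   <- prepare_system(topo, ffp, dp, target_side = 13,
                       equil_steps = 5e4, seed = 1)
idx  <- topo$methylated_range[1]:topo$methylated_range[2]
rg0  <- radius_of_gyration(st$positions, idx)
out  <- mcmd_cycle(st, topo, pb_pre = 1, ffp, dp, n_steps = 8e4, seed = 2)
rg1  <- mean(vapply(out$frames, radius_of_gyration, numeric(1),
                    indices = idx))
cat(sprintf("locus Rg: %.2f -> %.2f sigma\n", rg0, rg1))
```

Output:

```
config 1: mean anchor distance 2.001
config 2: mean anchor distance 1.757
config 3: mean anchor distance 1.521
locus Rg: 3.52 -> 1.53 sigma
```

The loop-model means show PRE pairs drawing statistically closer as their
looping directions become restricted by the surrounding chromatin type
(2.00 → 1.76 → 1.52 line units). The folding run shows the methylated
core collapsing once both PREs are PRC1-occupied — here from
$R_g = 3.5\sigma$ to $1.5\sigma$ within a single occupancy cycle of the
small demonstration locus.

Full experiment drivers: `run_pbpre_scan()` (occupancy scan with
confidence intervals), `run_eps_scan()` (distance maps across attraction
strengths at permanent occupancy), `run_dilution()` (post-replication
demethylation), `run_controls()` (no-PRE / no-methylation layouts), and
`build_inv_en()` for edge-positioned PRE layouts. A thin command-line
wrapper with the cheap subcommands lives at `inst/cli/polyfold`.

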