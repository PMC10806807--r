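# United-atom van der Waals parameters for the 12-6 Lennard-Jones
# stacking term:  E = eps_ij [ (rmin_ij / r)^12 - 2 (rmin_ij / r)^6 ]
# with Lorentz-Berthelot combination (rmin_ij = rmin_half_i + rmin_half_j,
# eps_ij = sqrt(eps_i * eps_j)).
#
# Generic united-atom literature values (nonpolar hydrogens folded into
# their heavy atoms); edit or replace to match the force field feeding the
# rest of your docking pipeline. Columns: type  epsilon(kcal/mol)  rmin_half(A)
C.ar    0.1200  1.9080
C.3     0.1094  1.9080
N       0.1700  1.8240
O       0.2100  1.6612
S       0.2500  2.0000
P       0.2000  2.1000
F       0.0610  1.7500
Cl      0.2650  1.9480
Br      0.3200  2.0200
I       0.4000  2.1500
H       0.0157  0.6000

# element -> default type fallbacks (atoms without explicit type labels)
default C  C.ar
default N  N
default O  O
default S  S
default P  P
default F  F
default Cl Cl
default Br Br
default I  I
default H  H
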