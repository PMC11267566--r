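# cleavescan simplified united-atom force field (self-consistent toy set)
# Units: nm, kJ/mol, degrees, elementary charges.
# [LJ] lists self-pair C12/C6; cross pairs combine geometrically.
# Ionizable side-chain beads (CBQ, CBN) are charge-neutralized, as in
# vacuum-tailored united-atom parameter sets; they differ from CBP only
# in bookkeeping.
# Bonds: E = k (b - b0)^2. Angles: E = k (theta - theta0)^2, keyed by the
# central atom type. Torsions: E = k (1 + cos(m phi - phase)), keyed by the
# central bond's type pair.

[LJ]
# type   C12            C6
N        2.305e-06      2.147e-03
H        1.000e-08      0.0
CA       1.087e-05      3.610e-03
C        3.820e-06      2.470e-03
O        1.280e-06      1.750e-03
CH3      1.850e-05      6.670e-03
CB       3.360e-05      8.190e-03
CBP      2.900e-05      9.630e-03
CBA      1.650e-04      1.990e-02
CBS      6.040e-05      1.470e-02
CBQ      2.900e-05      9.630e-03
CBN      2.900e-05      9.630e-03
WAL      1.000e-07      2.000e-03

[CHARGES]
N       -0.31
H        0.31
CA       0.00
C        0.45
O       -0.45
CH3      0.00
CB       0.00
CBP      0.00
CBA      0.00
CBS      0.00
CBQ      0.00
CBN      0.00
WAL      0.00

[BONDS]
# type_a type_b  k            b0
C        N       150000       0.133
CA       N       150000       0.147
C        CA      150000       0.153
C        O       180000       0.123
H        N       180000       0.100
CA       CB      150000       0.153
CA       CBP     150000       0.153
CA       CBA     130000       0.200
CA       CBS     150000       0.153
CA       CBQ     150000       0.153
CA       CBN     150000       0.153
C        CH3     150000       0.152
CH3      N       150000       0.147

[ANGLES]
# center k        theta0
N        200      120.0
CA       150      110.0
C        220      120.0

[TORSIONS]
# type_a type_b  k       mult  phase
C        N       33.5    2     180.0
CA       N       1.0     3     0.0
C        CA      1.0     3     0.0
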