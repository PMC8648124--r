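CST::BEGIN
  TEMPLATE::   ATOM_MAP: 1 atom_name: C1 C2 C3
  TEMPLATE::   ATOM_MAP: 1 residue3: LIG

  TEMPLATE::   ATOM_MAP: 2 atom_name: CB CA N
  TEMPLATE::   ATOM_MAP: 2 residue3: ALA

  CONSTRAINT:: distanceAB:    4.71    0.05   100.0     0     0
  CONSTRAINT::    angle_A:   88.49   10.00   100.0   360     1
  CONSTRAINT::    angle_B:  154.29   10.00   100.0   360     1
  CONSTRAINT::  torsion_A: -101.37   10.00   100.0   360     1
  CONSTRAINT:: torsion_AB:   -6.31   10.00   100.0   360     1
  CONSTRAINT::  torsion_B: -119.88   10.00   100.0   360     1
CST::END

CST::BEGIN
  TEMPLATE::   ATOM_MAP: 1 atom_name: C2 C1 C3
  TEMPLATE::   ATOM_MAP: 1 residue3: LIG

  TEMPLATE::   ATOM_MAP: 2 atom_name: C O CA
  TEMPLATE::   ATOM_MAP: 2 residue3: ALA

  CONSTRAINT:: distanceAB:    3.38    0.05   100.0     0     0
  CONSTRAINT::    angle_A:  144.05   10.00   100.0   360     1
  CONSTRAINT::    angle_B:   89.28   10.00   100.0   360     1
  CONSTRAINT::  torsion_A:  144.91   10.00   100.0   360     1
  CONSTRAINT:: torsion_AB:  133.97   10.00   100.0   360     1
  CONSTRAINT::  torsion_B:  -75.28   10.00   100.0   360     1
CST::END

CST::BEGIN
  TEMPLATE::   ATOM_MAP: 1 atom_name: C2 C1 C3
  TEMPLATE::   ATOM_MAP: 1 residue3: LIG

  TEMPLATE::   ATOM_MAP: 2 atom_name: N CA CB
  TEMPLATE::   ATOM_MAP: 2 residue3: ALA

  CONSTRAINT:: distanceAB:    3.89    0.05   100.0     0     0
  CONSTRAINT::    angle_A:  143.36   10.00   100.0   360     1
  CONSTRAINT::    angle_B:  112.06   10.00   100.0   360     1
  CONSTRAINT::  torsion_A:  111.71   10.00   100.0   360     1
  CONSTRAINT:: torsion_AB: -140.02   10.00   100.0   360     1
  CONSTRAINT::  torsion_B:    0.60   10.00   100.0   360     1
CST::END

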