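  Northwest   Computational   Chemistry    Package   (NWChem)  7.0   
  -----------------------------------------------------  

    Job    title:   water    


    Output  coordinates   in    angstroms   (scale  by    1.889725989   to    convert    to  a.u.)   

   No.  Tag    Charge  X   Y Z    
   ----  ----------------  ----------   --------------  --------------    --------------  
    1   O    8.0000    0.00000000 0.00000000   0.00000000  
    2 H   1.0000 0.75700000 0.58600000    0.00000000 
 3  H    1.0000 -0.75700000   0.58600000 0.00000000   

  ao    basis    = "sto-3g"    

  NWChem   SCF    Module  
  -----------------  

    Total   SCF    energy  =   -74.965901000000 


    Output  coordinates   in angstroms (scale    by    1.889725989  to   convert    to    a.u.)    

  No.  Tag    Charge X  Y  Z 
    ----  ----------------    ----------   -------------- -------------- --------------    
  1    O  8.0000    0.00000000    0.00000000 0.00000000   
 2    H   1.0000    0.75700000   0.58600000  0.00000000 
 3 H    1.0000   -0.75700000    0.58600000    0.00000000  

 ao  basis =    "sto-3g" 

   NWChem SCF  Module    
  -----------------   

    Total    SCF energy    =  -74.965901000000    

    NWChem Nuclear  Hessian   and  Frequency Analysis   
  ---------------------------------------------------------------------------- 
   Normal   Eigenvalue   ||  Projected   Infra    Red  Intensities  
    Mode [cm**-1] || [atomic    units] [(debye/angs)**2]    [(KM/mol)]   [arbitrary]  
   ------    ----------   || --------------   -----------------  ----------    -----------  
    1 1595.000  ||    0.000000 0.000  65.000 0.000    
  2   3657.050   ||    0.000000 0.000   4.000    0.000  
   3    3755.930  || 0.000000   0.000  50.000  0.000    

  Total  times cpu:  0.1s   wall: 0.1s    
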