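"material","energy_MeV","range_cm"
"water",50,2.2146477
"water",60,3.0800579
"water",70,4.0668913
"water",80,5.1695882
"water",90,6.3831436
"water",100,7.7029893
"water",110,9.1249126
"water",120,10.645
"water",130,12.259593
"water",140,13.965258
"water",150,15.758758
"water",160,17.637034
"water",170,19.597186
"water",180,21.636461
"water",190,23.752235
"water",200,25.942013
"water",210,28.203408
"water",220,30.534142
"water",230,32.932034
"water",240,35.394995
"water",250,37.921023
"lexan",50,1.9365428
"lexan",60,2.6935393
"lexan",70,3.5568106
"lexan",80,4.5214952
"lexan",90,5.5832163
"lexan",100,6.7379782
"lexan",110,7.9820964
"lexan",120,9.3121471
"lexan",130,10.724931
"lexan",140,12.217442
"lexan",150,13.78685
"lexan",160,15.430478
"lexan",170,17.145788
"lexan",180,18.930371
"lexan",190,20.781932
"lexan",200,22.698286
"lexan",210,24.677346
"lexan",220,26.717117
"lexan",230,28.815691
"lexan",240,30.971239
"lexan",250,33.182011
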