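name,unit,description
w_top,mm,top-view silhouette width
h_top,mm,top-view silhouette height
w_side,mm,side-view silhouette width
h_side,mm,side-view silhouette height
d_mean,mm,arithmetic mean of the four dimensions
v_ellip_avg,mL,ellipsoid volume proxy (4/3)*pi*a*b*c_avg
v_ellip_sw,mL,ellipsoid volume proxy with c = w_side/2
v_ellip_sh,mL,ellipsoid volume proxy with c = h_side/2
v_sphere,mL,volume of the sphere with the mean diameter
a_top,mm2,top-view elliptical cross-section area pi*a*b
a_side,mm2,side-view elliptical cross-section area pi*c_sw*c_sh
p_top,mm,Ramanujan perimeter of the top-view ellipse
p_side,mm,Ramanujan perimeter of the side-view ellipse
s_avg,mm2,Knud-Thomsen surface area on (a; b; c_avg) with p = 1.6075
psi_avg,dimensionless,sphericity pairing v_ellip_avg with s_avg
sa_to_v,mm2 per mL,surface-to-volume ratio s_avg / v_ellip_avg
ar_top,dimensionless,top-view aspect ratio w_top / h_top
ar_side,dimensionless,side-view aspect ratio w_side / h_side
ratio_w,dimensionless,cross-view width ratio w_top / w_side
ratio_h,dimensionless,cross-view height ratio h_top / h_side
area_ratio,dimensionless,cross-section area ratio a_top / a_side
e_top,dimensionless,top-view ellipse eccentricity sqrt(1 - (minor/major)^2)
e_side,dimensionless,side-view ellipse eccentricity
ix_atop_wside,mm3,interaction term a_top * w_side
ix_aside_htop,mm3,interaction term a_side * h_top
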